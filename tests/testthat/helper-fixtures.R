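# shared fixtures: small mixing spaces and independent geometry oracle

tef_zero <- function() {
  tibble::tibble(
    trophic_class = c("vegetable", "animal"),
    d13C_mean = 0, d13C_sd = 0, d15N_mean = 0, d15N_sd = 0
  )
}

# two isotopically distinct sources, zero TEF, known concentrations
two_source_space <- function(sd13 = 1, sd15 = 1,
                             q_c = c(40, 50), q_n = c(2, 3)) {
  cats <- tibble::tibble(
    category = c("A", "B"), trophic_class = "vegetable", n = c(10, 10),
    mean_d13C = c(-30, -20), sd_d13C = sd13,
    mean_d15N = c(0, 5), sd_d15N = sd15,
    digest_c = q_c, digest_n = q_n
  )
  build_mixing_space(cats, tefs = tef_zero())
}

# well-separated triangle of sources for polygon geometry tests
triangle_space <- function(sd = 0) {
  cats <- tibble::tibble(
    category = c("A", "B", "C"), trophic_class = "vegetable", n = 5,
    mean_d13C = c(-30, -20, -25), sd_d13C = sd,
    mean_d15N = c(0, 0, 10), sd_d15N = sd,
    digest_c = 45, digest_n = 3
  )
  build_mixing_space(cats, tefs = tef_zero())
}

# independent point-in-polygon oracle: crossing-number ray casting
ray_cast_inside <- function(px, py, hx, hy) {
  n <- length(hx)
  vapply(seq_along(px), function(m) {
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if ((hy[i] > py[m]) != (hy[j] > py[m])) {
        xint <- hx[i] + (py[m] - hy[i]) / (hy[j] - hy[i]) * (hx[j] - hx[i])
        if (px[m] < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# write a scenario's source samples to a temp CSV in the read_sources schema
write_sources_csv <- function(samples, path = tempfile(fileext = ".csv")) {
  utils::write.csv(samples, path, row.names = FALSE)
  path
}
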