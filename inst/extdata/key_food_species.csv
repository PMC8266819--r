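category,species,trophic_class,n,d13C_mean,d13C_sd,d15N_mean,d15N_sd,C_mean,C_sd,N_mean,N_sd
Herbs,Chenopodium bonus-henricus,vegetable,3,-28.8,0.8,-2.3,1.4,46.2,1.0,5.1,1.4
Herbs,Compositae,vegetable,13,-31.0,1.9,-2.2,1.8,45.2,1.8,2.4,0.6
Herbs,Graminacea,vegetable,28,-29.7,1.4,-2.7,1.8,46.2,1.9,2.4,1.3
Herbs,Trifolium thalii,vegetable,9,-30.3,1.1,-1.0,0.6,45.7,1.4,3.4,0.6
Herbs,Umbrelliferae,vegetable,10,-30.2,1.9,-1.9,2.4,45.5,1.3,2.3,0.3
Hard mast,Fagus sylvatica,vegetable,6,-28.1,1.9,-0.8,2.0,54.6,4.0,3.7,0.8
Hard mast,Quercus cerris,vegetable,6,-27.2,2.0,-3.2,0.9,45.6,0.6,0.7,0.1
Hard mast,Quercus pubescens,vegetable,6,-27.6,0.8,0.4,1.7,44.9,1.0,1.4,1.2
Wild fleshy fruits,Cornus mas,vegetable,3,-28.2,2.1,-5.6,0.6,42.8,0.3,0.4,0.1
Wild fleshy fruits,Crataegus monogyna,vegetable,4,-26.7,0.8,-3.0,1.0,44.4,0.9,0.6,0.1
Wild fleshy fruits,Fragaria vesca,vegetable,5,-29.1,2.4,-3.0,2.7,48.8,1.5,1.4,0.3
Wild fleshy fruits,Malus sylvestris,vegetable,5,-26.9,0.9,-3.2,1.3,44.9,0.6,0.4,0.2
Wild fleshy fruits,Prunus spinosa,vegetable,4,-28.2,1.0,-1.9,2.5,48.9,1.8,0.7,0.4
Wild fleshy fruits,Pyrus pyraster,vegetable,3,-27.3,0.1,-1.9,1.3,46.7,3.0,0.6,0.0
Wild fleshy fruits,Rhamnus alpina,vegetable,7,-27.4,1.0,-2.4,2.0,45.2,0.7,0.7,0.1
Wild fleshy fruits,Rosa canina,vegetable,5,-26.2,0.8,-2.3,3.5,45.0,1.2,0.9,0.3
Wild fleshy fruits,Rubus idaeus,vegetable,4,-29.9,1.2,-3.6,1.6,51.0,1.3,1.3,0.2
Wild fleshy fruits,Rubus ulmifolius,vegetable,6,-28.6,0.9,-0.9,1.7,49.4,2.8,1.2,0.3
Cultivated fleshy fruits,Ficus carica,vegetable,3,-28.5,0.3,-1.5,0.2,45.4,1.3,1.0,0.2
Cultivated fleshy fruits,Malus domestica,vegetable,4,-25.8,1.5,0.5,2.3,43.5,0.3,0.4,0.2
Cultivated fleshy fruits,Prunus domestica,vegetable,3,-28.3,1.5,3.7,1.3,43.0,0.5,0.9,0.4
Cultivated fleshy fruits,Pyrus communis,vegetable,6,-26.9,0.6,0.1,2.3,42.7,0.7,0.3,0.1
Cultivated vegetables,Cichorium intybus,vegetable,3,-28.5,0.3,10.6,3.2,37.2,2.3,2.5,0.4
Cultivated vegetables,Daucus carota,vegetable,3,-26.4,1.0,4.4,0.5,40.7,1.5,1.4,0.2
Cultivated vegetables,Eruca vesicaria,vegetable,3,-29.0,0.3,10.5,0.7,34.7,4.0,4.2,0.7
Cultivated vegetables,Lactuga sativa,vegetable,3,-30.0,0.1,10.5,2.7,39.3,4.4,3.5,1.6
Ungulates,Bos taurus,animal,1,-25.5,0.2,2.2,0.6,49.3,1.1,3.6,0.2
Ungulates,Capra hircus,animal,1,-24.1,0.0,3.7,0.2,48.1,0.7,3.5,0.0
Ungulates,Cervus elaphus,animal,3,-26.3,1.0,3.9,1.4,53.2,6.6,5.2,3.5
Ungulates,Ovis aries,animal,1,-23.1,0.0,7.8,0.9,46.2,0.9,3.4,0.1
Ungulates,Sus scrofa,animal,1,-25.3,0.0,4.5,0.3,49.1,1.5,3.5,0.1
Formicidae,Formicidae,animal,26,-26.6,1.2,1.7,1.1,52.0,5.5,9.4,1.7
C4,Zea mays,vegetable,3,-11.9,0.4,4.3,1.5,45.6,0.5,17.4,2.3
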