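season,model,looic,se_looic,delta_looic,se_delta,weight
spring,Status+BearID,168.0,23.5,0.0,NA,0.548
spring,Sex+BearID,169.1,22.2,1.1,3.8,0.316
spring,BearID,170.8,23.3,2.8,2.8,0.135
spring,Sex+Status,197.6,29.3,29.6,12.1,0
spring,Status,198.3,28.5,30.3,11.4,0
spring,Null,207.1,25.4,39.1,12.1,0
spring,Sex,210.3,24.9,42.3,11.8,0
early_summer,Status+BearID,176.8,16.9,0.0,NA,0.698
early_summer,BearID,179.1,17.4,2.3,3.5,0.221
early_summer,Sex+BearID,181.1,17.3,4.3,3.7,0.081
early_summer,Sex+Status,221.2,19.6,44.4,10.6,0
early_summer,Status,226.9,21.3,50.1,10.7,0
early_summer,Sex,238.6,23.8,61.8,13.0,0
early_summer,Null,241.9,26.1,65.1,15.2,0
late_summer,BearID,210.7,16.7,0.0,NA,0.558
late_summer,Sex+BearID,211.4,16.2,0.7,1.0,0.393
late_summer,Status+BearID,215.6,16.1,4.9,5.2,0.048
late_summer,Sex+Status,223.3,17.1,12.6,9.7,0.001
late_summer,Status,237.8,17.7,27.1,10.6,0
late_summer,Null,255.5,18.2,44.8,6.1,0
late_summer,Sex,257.8,17.9,47.1,6.3,0
autumn,Status+BearID,81.8,9.0,0.0,NA,0.362
autumn,Sex+BearID,82.0,9.0,0.2,0.5,0.327
autumn,BearID,82.1,9.2,0.3,0.6,0.311
autumn,Sex+Status,120.0,9.4,38.2,4.7,0
autumn,Status,122.7,9.4,40.9,5.1,0
autumn,Null,127.2,9.3,45.4,3.7,0
autumn,Sex,128.4,9.2,46.6,3.3,0
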