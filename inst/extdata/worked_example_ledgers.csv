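cell,electrochemical,in_lactate_c,in_lactate_e,in_butyrate_c,in_butyrate_e,charge_e,out_lactate_c,out_lactate_e,out_acetate_c,out_acetate_e,out_propionate_c,out_propionate_e,out_butyrate_c,out_butyrate_e,out_h2_e,out_co2_c,printed_cb,printed_eb,printed_eta
LB1,TRUE,36.6,146.5,9.9,49.5,123.8,2.5,9.9,7.9,31.6,12.8,59.6,9.0,45.0,71.0,0.7,70.6,67.9,1.36
LB2,TRUE,38.6,154.3,9.7,48.4,94.1,2.5,9.9,8.8,35.2,11.5,53.4,5.5,27.7,0.0,0.2,58.9,42.5,1.06
L1,TRUE,22.3,89.4,0,0,34.7,0.0,0.0,5.5,22.0,6.8,31.5,0.4,2.0,NA,NA,56.6,44.7,0.63
L2,TRUE,23.0,92.2,0,0,83.9,0.0,0.0,5.6,22.2,8.0,37.1,0.3,1.7,NA,NA,60.1,34.7,1.38
L3,TRUE,66.9,267.5,0,0,36.9,7.6,30.3,12.4,49.7,29.1,135.8,7.3,36.4,NA,NA,84.3,82.8,0.17
C_LB1_pH5,FALSE,9.0,36.0,11.4,57.0,0,6.4,25.8,0.2,0.7,0.1,0.3,10.2,51.0,NA,NA,82.9,83.7,NA
C_LB2_pH5,FALSE,8.8,35.2,11.0,54.9,0,2.9,11.6,1.3,5.4,0.1,0.5,10.7,53.3,NA,NA,76.0,78.7,NA
C_LB1_pH7,FALSE,9.0,36.0,12.0,59.8,0,0.1,0.2,2.5,10.0,3.9,18.2,11.1,55.4,NA,NA,83.7,87.5,NA
C_LB2_pH7,FALSE,9.2,36.7,12.0,59.8,0,0.1,0.3,2.5,10.1,3.5,16.5,9.5,47.3,NA,NA,73.9,77.0,NA
C_L1_pH5,FALSE,9.0,36.0,0,0,0,1.0,3.9,1.5,6.0,2.0,9.4,2.0,10.0,NA,NA,72.4,81.7,NA
C_L2_pH5,FALSE,8.9,35.5,0,0,0,0.1,0.3,2.2,8.7,1.4,6.6,2.6,13.0,NA,NA,70.7,80.7,NA
C_L1_pH7,FALSE,8.5,34.2,0,0,0,0.0,0.2,2.1,8.4,3.0,14.2,0.0,0.0,NA,NA,60.5,66.5,NA
C_L2_pH7,FALSE,9.2,36.9,0,0,0,0.1,0.2,2.2,8.7,4.1,19.3,0.1,0.5,NA,NA,70.2,77.9,NA
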