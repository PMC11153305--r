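"participant_id","timepoint_months","hba1c_mmol_mol","weight_kg","drug_1_name","drug_1_dose","drug_2_name","drug_2_dose","arm","sex","weight_stratum","compliance_flag","glucose_0","insulin_0","glucose_30","insulin_30","glucose_60","insulin_60","glucose_90","insulin_90","glucose_120","insulin_120"
"P0001",0,51.5,93.4,"metformin",1000,,,"FMD","M","upto100kg",TRUE,6.3,238.7,10.1,2090.2,11.3,3713.2,10.5,2715.8,8.7,1594.1
"P0001",6,52,89.6,"metformin",1000,,,"FMD","M","upto100kg",TRUE,6.3,238.7,9.8,2147,11.2,3067,10.1,2451.8,8.5,1475.4
"P0001",12,55.1,91.4,"metformin",1500,,,"FMD","M","upto100kg",TRUE,6.3,238.7,9.6,2286.5,10.9,3561.4,9.9,2678.9,8.7,1561.8
"P0002",0,60.6,114.6,"metformin",1000,,,"control","M","over100kg",TRUE,3.8,62.2,7.1,728.4,8.7,1070.9,7.7,825.3,6,516.3
"P0002",6,56.9,113.1,"metformin",1500,,,"control","M","over100kg",TRUE,3.8,62.2,7.4,719.5,8.6,1045.1,7.8,942.7,6.1,509.3
"P0002",12,58.5,113.8,"metformin",2000,,,"control","M","over100kg",TRUE,3.8,62.2,7.2,846.9,8.3,1066.4,7.7,840.8,6.2,538.4
"P0003",0,56.9,100.4,"metformin",1000,,,"FMD","M","over100kg",TRUE,7.3,183.9,10.6,1082.1,12,1589.3,11.2,1187.1,9.5,743.3
"P0003",6,46.3,96.4,"metformin",500,,,"FMD","M","over100kg",TRUE,7.3,183.9,10.9,1038.1,12.2,1376.6,11.3,1238.1,9.7,850
"P0003",12,44.9,99.9,"metformin",500,,,"FMD","M","over100kg",TRUE,7.3,183.9,10.9,1075,12.4,1489.9,11.4,1196.8,9.7,721.3
"P0004",0,50.5,98.7,"metformin",500,,,"control","M","upto100kg",TRUE,8.1,76.9,11.5,622.5,13,875.5,11.9,692.6,10.4,444.5
"P0004",6,38,96.9,"metformin",500,,,"control","M","upto100kg",TRUE,8.1,76.9,11.6,640.1,13.1,837.2,11.9,713.2,10.5,437.7
"P0004",12,48.3,102.5,"metformin",500,,,"control","M","upto100kg",TRUE,8.1,76.9,11.5,641.2,13.1,904.6,11.9,731.9,10.5,432
"P0005",0,37.5,105.8,,,,,"FMD","M","over100kg",FALSE,11.5,249.6,14.9,2584.6,16.5,3436.8,15.5,2886.9,14,1782.2
"P0005",6,38.5,100.2,,,,,"FMD","M","over100kg",FALSE,11.5,249.6,15.2,2534.3,16.6,3287.1,15.8,2770.8,13.8,1630.6
"P0005",12,29,100.6,,,,,"FMD","M","over100kg",FALSE,11.5,249.6,15.1,2313.6,16.9,3564.2,15.4,3098.3,13.7,1825.5
"P0006",0,46.7,103.6,,,,,"control","M","over100kg",TRUE,11.5,157,14.8,1091.3,16.1,1606.5,15.2,1268.2,13.7,888
"P0006",6,43.1,102.5,,,,,"control","M","over100kg",TRUE,11.5,157,15.1,1066.6,16.1,1415.5,15.7,1170.5,13.7,821.5
"P0006",12,42.3,103.4,,,,,"control","M","over100kg",TRUE,11.5,157,15,1137.4,16.2,1530.5,15.7,1214.8,13.7,831.8
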