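"sample_id","group","age","sex","tanner","height_cm","weight_kg","bmi","bmi_sds"
"T1DM_1","T1DM",17.2,"M",5,167,54,19.4,-0.38
"T1DM_2","T1DM",15,"F",5,159,58,22.9,1.01
"T1DM_3","T1DM",11.4,"M",2,152,37,16,-0.52
"T1DM_4","T1DM",10,"F",1,148,34.5,15.8,-0.31
"T1DM_5","T1DM",8.7,"F",1,140,33.2,16.9,0.59
"T1DM_6","T1DM",11.8,"M",2,149,40.5,18.2,0.37
"T1DM_7","T1DM",10.1,"M",1,139.5,30,15.4,-0.53
"CTRL_1","control",15,"M",5,172.8,58.9,19.7,0.23
"CTRL_2","control",9.9,"M",1,139,30.3,15.7,-0.38
"CTRL_3","control",11.6,"M",1,147,42.2,19.5,0.92
"CTRL_4","control",12.6,"F",2,158.7,40.9,16.2,-0.81
"CTRL_5","control",12.5,"F",3,151.9,41,17.8,-0.11
"CTRL_6","control",17.8,"F",5,168.4,60.1,21.2,0.14
"CTRL_7","control",15.2,"M",4,179.1,64.1,20,0.32
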