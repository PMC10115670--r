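id,sex,age,height_cm,weight_kg,bmi,site,f_latent,dxa_tscore,rems_tscore,fractured,fracture_type,time_to_event_y
P001,F,71,158,61,24.44,lumbar,0.55,-2.8,-2.9,TRUE,major_osteoporotic,2.3
P002,F,59,160,62,24.22,lumbar,0.28,-1.2,-1.0,FALSE,none,4.1
P003,M,48,174,78,25.76,lumbar,0.18,-0.5,-0.6,FALSE,none,3.6
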