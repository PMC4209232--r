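episode_id,patient_id,hospital_id,age,gender,female,diabetes,obesity,hypertension,osteoporosis,obesity_index,antiplatelet,anticoagulants,inr_cat,inr_out_of_range,inr_missing,outcome
A020,P20,H4,80,F,1,0,0,0,0,0,0,0,in_range,0,0,1
A021,P21,H5,70,F,1,0,0,0,0,0,0,0,out_of_range,1,0,0
A030,P29,H5,90,M,0,0,0,0,0,0,0,0,missing,0,1,0
A032,P31,H5,85,F,1,0,0,0,1,0,1,0,in_range,0,0,1
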