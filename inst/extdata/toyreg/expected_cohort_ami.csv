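episode_id,patient_id,hospital_id,age,gender,female,cancer,diabetes,lipid_disorders,blood_disorders,previous_ami,heart_failure,other_ischemic,chronic_renal,chronic_liver_pancreas_intestine,previous_cabg,previous_pci,blood_disorders_index,other_ischemic_index,anticoagulants,antiplatelet,cardiac_therapy,antihypertensives,diuretics,beta_blockers,calcium_channel_blockers,ace_inhibitors,arb,statins,other_lipid_modifying,antidiabetics,sbp_cat,sbp_le100,sbp_missing,outcome
A001,P01,H1,65,M,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,le100,1,0,1
A003,P02,H2,50,F,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,gt100,0,0,0
A006,P03,H1,80,F,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,missing,0,1,1
A010,P07,H2,70,M,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,gt100,0,0,0
A012,P09,H3,55,M,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,gt100,0,0,0
A014,P09,H3,55,M,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,gt100,0,0,0
A015,P10,H1,75,F,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,gt100,0,0,0
A017,P11,H2,68,M,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,le100,1,0,0
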