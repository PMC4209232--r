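admission_key,sbp,inr,creatinine
A001,95,,
A003,130,,
A004,118,,
A006,,,
A008,99,,
A010,115,,
A011,140,,
A012,105,,
A013,120,,
A014,125,,
A015,120,,
A017,100,,
A018,122,,
A020,,1.1,0.9
A021,,1.3,1.1
A022,,1.0,1.0
A024,,1.1,0.8
A025,,1.0,1.2
A026,,1.1,0.9
A027,,1.0,1.3
A028,,1.1,1.0
A029,,,1.5
A030,,,1.2
A031,,1.0,0.9
A032,,1.0,1.0
A034,,1.1,1.1
A036,,1.0,1.0
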