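patient_id,death_date
P01,2010-03-20
P03,2010-05-31
P07,2010-07-02
P28,2010-09-02
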