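patient_id,dispensing_date,atc
P01,2010-02-28,C09AA05
P02,2010-04-01,C03AA01
P07,2010-05-15,C07AB02
P07,2010-02-21,C10AA05
P09,2010-02-01,C10AA07
P10,2010-07-01,C09CA01
P31,2010-08-11,B01AC06
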