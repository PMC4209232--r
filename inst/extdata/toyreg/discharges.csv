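admission_id,patient_id,hospital_id,admission_date,admission_time,discharge_date,principal_dx,secondary_dx,procedures,drg,disposition,age,gender,resident,icu_admission
A001,P01,H1,2010-03-10,08:30,2010-03-20,41071,,,122,died,65,M,TRUE,FALSE
A002,P01,H1,2009-03-10,12:00,2009-03-13,2500,,,467,discharged,64,M,TRUE,FALSE
A003,P02,H2,2010-04-01,09:15,2010-04-08,41001,,,122,discharged,50,F,TRUE,FALSE
A004,P02,H2,2010-04-21,14:00,2010-04-26,41011,,,122,discharged,50,F,TRUE,FALSE
A005,P02,H3,2008-01-01,12:00,2008-01-04,2500,,,467,discharged,48,F,TRUE,FALSE
A006,P03,H1,2010-05-01,22:40,2010-05-08,4271,4109,,122,discharged,80,F,TRUE,FALSE
A007,P04,H2,2010-06-15,11:00,2010-06-22,4275,4109,,122,discharged,72,M,TRUE,FALSE
A008,P05,H1,2010-07-01,10:00,2010-07-06,41090,,,122,discharged,17,M,TRUE,FALSE
A009,P06,H3,2010-07-10,16:30,2010-07-18,4101,,,122,discharged,66,F,FALSE,FALSE
A010,P07,H2,2010-06-01,07:50,2010-06-10,41041,2849,,122,discharged,70,M,TRUE,FALSE
A011,P08,H1,2010-08-01,12:00,2010-08-09,41001,,,122,discharged,60,,TRUE,FALSE
A012,P09,H3,2010-01-05,12:00,2010-01-12,41011,,,122,discharged,55,M,TRUE,FALSE
A013,P09,H3,2010-01-25,12:00,2010-01-30,41011,,,122,discharged,55,M,TRUE,FALSE
A014,P09,H3,2010-02-14,12:00,2010-02-21,41011,,,122,discharged,55,M,TRUE,FALSE
A015,P10,H1,2010-08-10,18:05,2010-08-19,41071,,,122,discharged,75,F,TRUE,FALSE
A016,P10,H2,2010-05-02,12:00,2010-05-06,4280,,,127,discharged,75,F,TRUE,FALSE
A017,P11,H2,2010-10-01,12:00,2010-10-08,41091,,,122,discharged,68,M,TRUE,FALSE
A018,P11,H2,2010-10-29,12:00,2010-11-03,41091,,,122,discharged,68,M,TRUE,FALSE
A019,P12,H1,2010-04-05,12:00,2010-04-11,4280,,,127,discharged,77,F,TRUE,FALSE
A020,P20,H4,2010-03-01,10:00,2010-03-10,82021,,8151:2010-03-02,236,discharged,80,F,TRUE,FALSE
A021,P21,H5,2010-04-01,13:20,2010-04-12,8208,,8151:2010-04-03,236,discharged,70,F,TRUE,FALSE
A022,P22,H4,2010-06-01,12:00,2010-06-10,82000,,8151:2010-06-02,236,discharged,82,F,TRUE,FALSE
A023,P22,H4,2009-06-01,12:00,2009-06-09,82000,,8151:2009-06-02,236,discharged,81,F,TRUE,FALSE
A024,P23,H5,2010-05-01,12:00,2010-05-09,82020,,8151:2010-05-02,209,discharged,64,F,TRUE,FALSE
A025,P24,H4,2010-05-10,12:00,2010-05-18,82021,,8151:2010-05-11,236,discharged,78,M,FALSE,FALSE
A026,P25,H5,2010-06-20,12:00,2010-06-29,82000,1629,8151:2010-06-21,236,discharged,74,F,TRUE,FALSE
A027,P26,H4,2010-07-01,12:00,2010-07-12,82002,,8151:2010-07-02,485,discharged,79,M,TRUE,FALSE
A028,P27,H5,2010-07-15,12:00,2010-07-24,82021,,8151:2010-07-16,236,discharged,88,F,TRUE,TRUE
A029,P28,H4,2010-09-01,12:00,2010-09-02,82000,,,236,died,91,F,TRUE,FALSE
A030,P29,H5,2010-08-01,12:00,2010-08-12,71945,8200,,236,discharged,90,M,TRUE,FALSE
A031,P30,H4,2010-08-20,12:00,2010-08-29,82021,,8151:2010-08-21,236,discharged,101,F,TRUE,FALSE
A032,P31,H5,2010-09-10,12:00,2010-09-19,82020,,7935:2010-09-10,236,discharged,85,F,TRUE,FALSE
A033,P31,H4,2009-11-15,12:00,2009-11-18,73300,,,243,discharged,84,F,TRUE,FALSE
A034,P32,H4,2010-10-01,12:00,2010-10-09,82021,,8151:2010-10-02,236,discharged,78,F,TRUE,FALSE
A035,P32,H4,2009-10-01,12:00,2009-10-05,1539,,,172,discharged,77,F,TRUE,FALSE
A036,P33,H5,2010-10-05,12:00,2010-10-12,82000,,8151:2010-10-06,236,discharged,64,M,FALSE,FALSE
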