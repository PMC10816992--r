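id,group,age,sex,mmse,apoe,ab42_plasma,ab40_plasma,ratio,csf_ab42,centiloid,blood_date,amyloid_date
P001,volunteer,62,female,29,e3e3,18.9,400,,,,2021-03-01,
P002,volunteer,71,male,28,e3e4,16.4,392,,410,,2021-03-08,2021-09-20
P003,ad,75,male,21,e3e4,15.2,380,,300,,2021-04-01,2021-05-01
P004,ad,78,female,23,e4e4,14.8,351,,,58,2021-04-12,2019-11-02
P005,non_ad,68,male,26,e2e3,20.1,395,,,12,2021-05-01,2021-06-10
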