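encounter_id,patient_id,hospital_id,admission_ts,discharge_ts,age_years,sex,race,ethnicity,code_status,comfort_care_ts
F01,P01,H1,2021-02-01T00:00:00Z,2021-02-03T00:00:00Z,67,female,White,other ethnicity,full,NA
F02,P02,H2,2021-02-01T12:00:00Z,2021-02-04T12:00:00Z,54,male,White,other ethnicity,full,NA
F03,P03,H1,2021-02-02T00:00:00Z,2021-02-03T12:00:00Z,81,female,Black or African American,other ethnicity,full,NA
F04,P04,H2,2021-02-02T12:00:00Z,2021-02-06T12:00:00Z,45,male,White,other ethnicity,full,NA
F05,P05,H1,2021-02-03T00:00:00Z,2021-02-05T12:00:00Z,72,female,Asian,other ethnicity,full,NA
F06,P06,H2,2021-02-03T12:00:00Z,2021-02-04T12:00:00Z,29,male,White,other ethnicity,full,NA
F07,P07,H1,2021-02-04T00:00:00Z,2021-02-07T12:00:00Z,60,female,American Indian or Alaska Native,other ethnicity,full,NA
F08,P08,H2,2021-02-04T12:00:00Z,2021-02-06T12:00:00Z,38,male,White,other ethnicity,full,NA
F09,P09,H1,2021-02-05T00:00:00Z,2021-02-06T06:00:00Z,76,female,White,other ethnicity,full,NA
F10,P10,H2,2021-02-05T12:00:00Z,2021-02-08T06:00:00Z,51,male,chose-not-to-answer,other ethnicity,full,NA
F11,P11,H1,2021-02-06T00:00:00Z,2021-02-08T06:00:00Z,63,female,White,Hispanic or Latino,DNR,NA
F12,P12,H2,2021-02-06T12:00:00Z,2021-02-08T04:00:00Z,44,male,White,other ethnicity,full,2021-02-06T22:00:00Z
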