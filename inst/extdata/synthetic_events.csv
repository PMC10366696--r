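encounter_id,event_type,ts
F02,icu_transfer,2021-02-02T18:00:00Z
F05,mechanical_ventilation,2021-02-03T20:00:00Z
F09,death,2021-02-06T06:00:00Z
F12,death,2021-02-08T04:00:00Z
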