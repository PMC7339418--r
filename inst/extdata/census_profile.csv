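gender,age_band,ses,proportion
female,16-24,general,12.24
female,25-44,general,20.67
female,45-64,general,14.65
female,65+,general,4.24
male,16-24,general,14.87
male,25-44,general,18.73
male,45-64,general,12.35
male,65+,general,2.25
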