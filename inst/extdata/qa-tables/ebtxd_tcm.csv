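# EBT-XD gamma pass rates (1%/1 mm), time-matched calibration curve (TCM)
# Five patient-specific QA cases; time in minutes postirradiation.
time_min,EBT-XD-1,EBT-XD-2,EBT-XD-3,EBT-XD-4,EBT-XD-5
5,99.1,99.4,99.8,99.6,99.9
10,99.1,99.9,99.7,99.9,99.9
15,99.1,100.0,100.0,99.3,99.9
20,99.4,100.0,100.0,99.3,99.9
25,99.6,100.0,99.8,99.9,99.9
30,99.7,100.0,100.0,99.3,99.8
60,99.9,100.0,100.0,99.6,99.9
120,100.0,100.0,99.6,99.7,99.9
180,100.0,100.0,99.9,99.9,100.0
240,100.0,100.0,100.0,99.8,100.0
300,100.0,100.0,100.0,99.9,100.0
600,100.0,100.0,99.9,99.9,100.0
720,100.0,100.0,100.0,99.5,100.0
840,100.0,100.0,100.0,99.9,99.9
960,100.0,100.0,100.0,100.0,100.0
1080,100.0,100.0,99.8,100.0,100.0
1200,100.0,100.0,100.0,100.0,100.0
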