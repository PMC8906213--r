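# EBT3 gamma pass rates (1%/1 mm), time-matched calibration curve (TCM)
# Five patient-specific QA cases; time in minutes postirradiation.
time_min,EBT3-1,EBT3-2,EBT3-3,EBT3-4,EBT3-5
5,98.0,87.3,89.0,97.3,99.5
10,99.5,97.9,94.5,99.2,99.9
15,99.7,98.6,97.4,99.6,100.0
20,99.8,99.5,98.3,99.7,100.0
25,99.7,99.8,99.1,99.8,100.0
30,99.8,99.9,99.5,99.9,100.0
60,99.2,100.0,99.9,100.0,100.0
120,99.7,100.0,99.9,100.0,100.0
180,99.0,100.0,100.0,100.0,100.0
240,99.9,100.0,100.0,100.0,100.0
300,99.7,100.0,100.0,100.0,100.0
600,99.9,100.0,100.0,100.0,100.0
720,99.9,100.0,100.0,100.0,100.0
840,99.9,100.0,100.0,100.0,100.0
960,99.8,100.0,100.0,100.0,100.0
1080,99.3,100.0,100.0,100.0,100.0
1200,100.0,100.0,100.0,100.0,100.0
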