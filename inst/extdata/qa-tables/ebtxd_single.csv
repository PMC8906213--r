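# EBT-XD gamma pass rates (1%/1 mm), single fixed calibration curve (20 h)
# Five patient-specific QA cases; time in minutes postirradiation.
time_min,EBT-XD-1,EBT-XD-2,EBT-XD-3,EBT-XD-4,EBT-XD-5
5,65.0,42.0,92.7,42.8,50.3
10,70.0,53.3,91.6,64.9,57.5
15,75.0,59.7,94.7,77.5,61.0
20,82.0,64.9,95.1,78.0,60.3
25,83.3,68.3,95.4,72.7,65.0
30,84.6,69.4,94.9,76.4,66.3
60,93.8,81.5,94.2,88.9,71.9
120,97.1,91.8,98.3,92.6,76.7
180,97.9,94.9,97.8,95.2,84.2
240,98.0,96.3,98.5,97.3,88.0
300,98.6,98.3,99.5,98.8,88.5
600,99.9,99.8,100.0,99.9,94.6
720,100.0,99.9,100.0,100.0,97.8
840,100.0,99.9,100.0,99.5,97.7
960,100.0,100.0,100.0,99.7,100.0
1080,100.0,100.0,100.0,100.0,100.0
1200,100.0,100.0,100.0,100.0,100.0
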