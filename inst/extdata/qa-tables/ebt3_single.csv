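# EBT3 gamma pass rates (1%/1 mm), single fixed calibration curve (20 h)
# Five patient-specific QA cases; time in minutes postirradiation.
time_min,EBT3-1,EBT3-2,EBT3-3,EBT3-4,EBT3-5
5,32.9,33.0,29.8,25.0,68.3
10,36.9,41.2,33.8,39.4,83.1
15,46.3,41.0,36.7,49.2,87.7
20,49.6,43.8,39.1,54.2,90.9
25,54.5,47.3,41.2,61.0,92.4
30,53.4,57.4,42.7,64.7,93.8
60,62.9,58.6,52.7,80.3,96.8
120,70.5,75.5,70.9,93.0,98.8
180,81.9,87.9,82.9,94.0,99.2
240,90.7,93.1,90.8,97.2,99.4
300,94.0,96.6,94.3,98.2,99.6
600,97.5,99.8,99.5,99.8,99.9
720,98.6,100.0,99.7,99.9,100.0
840,98.8,100.0,99.9,100.0,100.0
960,99.7,100.0,100.0,100.0,100.0
1080,99.9,100.0,100.0,100.0,100.0
1200,100.0,100.0,100.0,100.0,100.0
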