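# Two-facility implementation trial: gamma pass rates (2%/1 mm) at
# arbitrary scan times postirradiation. "true" is the pass rate from each
# facility's established methodology and usual scan time; it applies to
# every scan time of that case.
case,t_post_min,tcm,single,true
Case 1,8,89.0,99.4,87.9
Case 1,18,83.9,99.3,87.9
Case 1,28,84.2,98.7,87.9
Case 1,58,85.2,97.8,87.9
Case 1,298,84.2,90.0,87.9
Case 1,598,84.0,87.9,87.9
Case 1,1198,88.0,88.0,87.9
Case 2,12,91.2,94.3,91.0
Case 2,22,89.8,96.6,91.0
Case 2,28,89.2,97.2,91.0
Case 2,58,89.6,96.9,91.0
Case 2,297,85.5,91.9,91.0
Case 2,597,89.7,91.9,91.0
Case 2,1197,91.7,91.0,91.0
Case 3 PTV 1,40,74.9,54.7,80.3
Case 3 PTV 2,30,96.7,86.8,97.8
Case 4 PTV 3,20,89.9,47.6,95.5
Case 5 PTV 2,30,97.5,87.0,99.1
Case 5 PTV 4,20,99.2,82.2,98.1
Case 6 PTV 2,40,90.2,77.3,94.9
Case 6 PTV 3,50,96.7,80.7,92.9
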