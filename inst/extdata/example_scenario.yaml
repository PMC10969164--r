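# Example synthetic scenario: 36 reference registries around
# y = 56 + 0.4 x (sigma 1.5 years), 41 sparse study areas, three of them
# with injected early-onset shifts.
n_reference: 36
x_range: [40, 50]
true_alpha: 56
true_beta: 0.4
true_sigma: 1.5
n_study: 41
shifts: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
         0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
         -8, 0, 0, 0, 0, 0, 0, 0, 0, 0,
         -5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 4]
study_case_counts: [1, 4, 15, 18, 11, 33, 0, 36, 60, 5,
                    14, 48, 2, 89, 3, 287, 8, 49, 46, 30,
                    30, 22, 17, 55, 70, 12, 9, 25, 40, 31,
                    30, 6, 19, 28, 44, 52, 13, 16, 21, 34, 27]
sd_onset: 9
seed: 20240318
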