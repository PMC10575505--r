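quantity,province,value
total_episodes,BC,118606
total_episodes,ON,317823
prescribed_episodes,BC,54782
prescribed_episodes,ON,164698
unique_patients,BC,51981
unique_patients,ON,138157
n_female,BC,29217
n_female,ON,90830
n_male,BC,25565
n_male,ON,73868
n_age_65_79,BC,32533
n_age_65_79,ON,105429
n_age_80_plus,BC,22249
n_age_80_plus,ON,59269
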