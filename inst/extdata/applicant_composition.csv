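section,characteristic,n,printed_pct,denominator
age_group,7-14,126268,26.0,485676
age_group,15-18,41647,8.6,485676
age_group,19-24,36463,7.5,485676
age_group,25-34,50967,10.5,485676
age_group,35-44,56232,11.6,485676
age_group,45-54,73712,15.2,485676
socio_demographic,women_girls,210274,43.3,485676
socio_demographic,indigenous,32866,6.8,485676
socio_demographic,low_ses,150472,31.0,485676
socio_demographic,regional_remote,159416,32.8,485676
age_group,55-64,100387,20.7,485676
disability_group,sensory,36197,7.5,485676
disability_code,hearing_impairment,22042,4.5,485676
disability_code,visual_impairment,10433,2.1,485676
disability_code,other_sensory_speech,3722,0.8,485676
disability_group,autism,125916,25.9,485676
disability_group,intellectual_other,91542,18.8,485676
disability_code,developmental_delay,337,0.1,485676
disability_code,trisomy_21,9369,1.9,485676
disability_code,intellectual_disability,81681,16.8,485676
disability_group,physical,66449,13.7,485676
disability_code,cerebral_palsy,13751,2.8,485676
disability_code,spinal_cord_injury,6013,1.2,485676
disability_code,other_physical,46685,9.6,485676
disability_group,psychosocial,82525,17.0,485676
disability_group,brain_injury_stroke,28164,5.8,485676
disability_code,acquired_brain_injury,18248,3.8,485676
disability_code,stroke,9916,2.0,485676
disability_group,other,54883,11.3,485676
disability_code,multiple_sclerosis,10929,2.3,485676
disability_code,other_neurological,26377,5.4,485676
disability_code,other,17577,3.6,485676
prior_support,australian_gov,37478,7.7,485676
prior_support,state_gov,161822,33.3,485676
prior_support,none,286376,59.0,485676
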