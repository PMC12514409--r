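strategy,crc_cases,cancer_life_years_lost,total_cost
none,3233,5635,225515010
fit_colo,3113,5355,264303185
fit_ai,3100,5327,263275923
colo,1879,3251,711728628
ai_colo,1733,2996,701769288
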