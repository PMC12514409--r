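parameter,value,provenance
tests.fit_sensitivity,0.73,FIT performance at 20 ug/g cutoff (published Asian screening estimates)
tests.fit_specificity,0.919,FIT performance at 20 ug/g cutoff (published Asian screening estimates)
compliance.fit,0.60,screening programme uptake (published Asian screening estimates)
compliance.colonoscopy_primary,0.989,screening programme uptake (published Asian screening estimates)
compliance.colonoscopy_after_positive,1.00,assumed full follow-up of positives
complications.polypectomy_rate,0.73,polypectomy rate after a positive FIT (published programme data)
complications.bleeding_rate,0.0098,per-colonoscopy bleeding rate (complication systematic review)
complications.perforation_rate,0.0008,per-colonoscopy perforation rate (complication systematic review)
complications.perforation_mortality,0.000029,per-perforation mortality (complication systematic review)
efficacy.fit,0.21,CRC incidence reduction by FIT (network meta-analysis)
efficacy.colonoscopy,0.442,CRC incidence reduction by conventional colonoscopy (published CEA)
efficacy.ai_colonoscopy,0.489,CRC incidence reduction by AI-assisted colonoscopy (published CEA)
incidence.rate.1,55.9,annual CRC incidence per 100000 ages 50-54 (Hong Kong Cancer Registry)
incidence.rate.2,89.8,annual CRC incidence per 100000 ages 55-59 (Hong Kong Cancer Registry)
incidence.rate.3,137,annual CRC incidence per 100000 ages 60-64 (Hong Kong Cancer Registry)
incidence.rate.4,200,annual CRC incidence per 100000 ages 65-69 (Hong Kong Cancer Registry)
incidence.rate.5,253.2,annual CRC incidence per 100000 ages 70-74 (Hong Kong Cancer Registry)
incidence.rate.6,330.5,annual CRC incidence per 100000 ages 75+ (Hong Kong Cancer Registry)
stages.distribution_raw.1,0.113,stage 1 share at diagnosis (registry data; renormalized in use)
stages.distribution_raw.2,0.254,stage 2 share at diagnosis (registry data; renormalized in use)
stages.distribution_raw.3,0.324,stage 3 share at diagnosis (registry data; renormalized in use)
stages.distribution_raw.4,0.310,stage 4 share at diagnosis (registry data; renormalized in use)
stages.annual_mortality.1,0.01,annual mortality of stage 1 CRC (registry data)
stages.annual_mortality.2,0.045,annual mortality of stage 2 CRC (registry data)
stages.annual_mortality.3,0.087,annual mortality of stage 3 CRC (registry data)
stages.annual_mortality.4,0.43,annual mortality of stage 4 CRC (registry data)
costs.fit_kit,19,one FIT kit in US dollars (government gazette)
costs.colonoscopy,1259,colonoscopy procedure in US dollars (government gazette)
costs.consultation,96,consultation fee in US dollars (government gazette)
costs.bleeding_episode,3320,bleeding hospitalization in US dollars (government gazette)
costs.histopathology,142,histopathological examination in US dollars (government gazette)
costs.perforation_episode,10790,perforation hospitalization in US dollars (government gazette)
costs.care_stage1,17071,stage 1 CRC care lump sum in US dollars (diagnosis + treatment + follow-up)
costs.care_stage2,19755,stage 2 CRC care lump sum in US dollars (diagnosis + treatment + follow-up)
costs.care_stage3,26883,stage 3 CRC care lump sum in US dollars (incl. 6 months FOLFOX)
costs.care_stage4,45115,stage 4 CRC care lump sum in US dollars (incl. 10 months FOLFOX+bevacizumab)
economics.discount_rate,0.03,annual discount rate for costs and life years
economics.cohort_size,100000,hypothetical average-risk cohort size
economics.start_age,50,screening entry age
economics.screening_stop_age,75,screening stop age
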