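year,incident_count,age_mean,age_sd,age_median,age_iqr,male_count,general_population
2017,46308,67.6,15.6,69,22,20562,3757600
2018,47684,68,15.7,69,22,22205,3781420
2019,47931,68.2,15.6,70,22,21812,3800000
2020,77222,66.4,15.7,68,21,35397,3801800
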