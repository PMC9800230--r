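year,prevalent_count,age_mean,age_sd,age_median,age_iqr,male_count,general_population
2017,156721,70.6,14.6,71,20,71381,3757600
2018,160498,70.7,14.6,72,20,73033,3781420
2019,164721,70.9,14.5,72,20,76207,3800000
2020,167751,71.1,14.4,72,20,77775,3801800
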