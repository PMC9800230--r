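year,chronic_on_jan1,no_refill_nov_dec,deaths_before_cutoff
2017,156721,19551,52
2018,160498,20761,71
2019,164721,21301,95
2020,167751,20809,131
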