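metric,value_2017,value_2020
gp_initiations,32962,67280
gp_physicians,6318,9820
other_specialty_physicians,61,122
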