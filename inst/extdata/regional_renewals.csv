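specialty,n
general_practitioner,2402263
institution,281311
specialist,5221
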