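inn,dosage_mg,ddd_mg
esomeprazole,10,30
esomeprazole,20,30
esomeprazole,40,30
lansoprazole,15,30
lansoprazole,30,30
omeprazole,10,20
omeprazole,20,20
pantoprazole,20,40
pantoprazole,40,40
rabeprazole,10,20
rabeprazole,20,20
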