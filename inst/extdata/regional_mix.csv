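inn,dosage_mg,pct_2017,pct_2018,pct_2019,pct_2020
esomeprazole,10,0.12,0.14,0.14,0.13
esomeprazole,20,22.31,22.03,21.87,21.67
esomeprazole,40,17.88,17.97,17.78,17.70
lansoprazole,15,6.75,7.11,7.70,8.18
lansoprazole,30,5.84,6,6.21,6.44
omeprazole,10,3.66,3.69,3.54,3.49
omeprazole,20,14.73,14.66,14.14,13.78
pantoprazole,20,12.02,12.17,12.65,12.79
pantoprazole,40,7.57,7.85,7.87,8.08
rabeprazole,10,3.74,3.38,3.20,2.96
rabeprazole,20,5.39,4.99,4.89,4.78
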