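"age","q_annual"
32,0.000478772297197394
33,0.000523848523718895
34,0.000573167442572742
35,0.000627128147086542
36,0.000686167224400291
37,0.000750762268580063
38,0.0008214357210653
39,0.000898759068579391
40,0.000983357431343701
41,0.00107591457735878
42,0.00117717840169307
43,0.00128796691315303
44,0.00140917477441949
45,0.00154178044574427
46,0.00168685398661794
47,0.00184556557446924
48,0.00201919480444879
49,0.00220914083970081
50,0.00241693348725014
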