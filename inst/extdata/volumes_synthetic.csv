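"year","volume"
2015,7e+05
2016,885333
2017,1070667
2018,1256000
2019,1441333
2020,1626667
2021,1812000
2022,1997333
2023,2182667
2024,2368000
2025,2553333
2026,2738667
2027,2924000
2028,3109333
2029,3294667
2030,3480000
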