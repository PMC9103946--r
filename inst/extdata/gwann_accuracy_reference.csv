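year,rmse,mre
1992,0.0117,0.0254
1995,0.0191,0.0420
1996,0.0468,0.1193
1997,0.0043,0.0105
1998,0.0261,0.0554
1999,0.0422,0.1026
2000,0.0261,0.0561
2001,0.0806,0.1521
2002,0.0658,0.1275
2003,0.1015,0.1895
2020,0.1546,0.2518
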