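"time","intensity","sigma"
0,1,0.02
96,0.495240225177751,0.02
192,0.27863953932352,0.02
288,0.220497389595444,0.02
384,0.187420773451999,0.02
480,0.184703841042483,0.02
576,0.159219210268086,0.02
672,0.132744732655318,0.02
768,0.143123521688107,0.02
864,0.110769807236654,0.02
960,0.117228361454908,0.02
1056,0.0826612180391608,0.02
1152,0.120039288758873,0.02
1248,0.0549543657191548,0.02
1344,0.0734144326074954,0.02
1440,0.0684535910300787,0.02
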