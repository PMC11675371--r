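gene,hgvs_p,significance,het,hom,hemi,sex
NLGN1,p.A87S,,,,,
NLGN1,p.P88S,,,,,
NLGN1,p.P89L,,,,,
NLGN1,p.T90R,,,,,
NLGN1,p.R93H,,,,,
NLGN1,p.E99Q,,,,,
NLGN1,p.P100S,,,,,
NLGN1,p.P103S,,,,,
NLGN3,p.A76T,,,,,
NLGN3,p.P77S,,,,,
NLGN3,p.I77M,,,,,
NLGN3,p.E81K,,,,,
NLGN3,p.K82Q,,,,,
NLGN3,p.R83C,,,,,
NLGN3,p.L85V,,,,,
NLGN4X,p.P81A,,,,,
NLGN4X,p.T83P,,,,,
NLGN4X,p.G84R,,,,,
NLGN4X,p.R87W,,,,,
NLGN4X,p.P90A,,,,,
NLGN4X,p.P94L,,,,,
NLGN4X,p.T98A,,,,,
NLGN4X,p.T103A,,,,,
NLGN4X,p.T104S,,,,,
NLGN4X,p.A108G,,,,,
NLGN4X,p.L114P,,,,,
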