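gene,hgvs_p,significance,het,hom,hemi,sex
NLGN1,p.T667K,,,,,
NLGN1,p.Q675R,,,,,
NLGN1,p.P678A,,,,,
NLGN1,p.T694A,,,,,
NLGN2,p.R641P,,,,,
NLGN2,p.R642W,,,,,
NLGN2,p.P645L,,,,,
NLGN2,p.E654K,,,,,
NLGN2,p.P655T,,,,,
NLGN3,p.T652A,,,,,
NLGN3,p.T659N,,,,,
NLGN3,p.R671W,,,,,
NLGN3,p.I674T,,,,,
NLGN3,p.N680D,,,,,
NLGN4X,p.S620L,,,,,
NLGN4X,p.T625I,,,,,
NLGN4X,p.T625N,,,,,
NLGN4X,p.R626Q,,,,,
NLGN4X,p.R627Q,,,,,
NLGN4X,p.W633R,,,,,
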