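gene,hgvs_p,significance,het,hom,hemi,sex
NLGN1,p.T674I,,,,,
NLGN1,p.V678I,,,,,
NLGN1,p.A681S,,,,,
NLGN1,p.A681V,,,,,
NLGN1,p.V682A,,,,,
NLGN1,p.L686M,,,,,
NLGN1,p.N690H,,,,,
NLGN1,p.I691M,,,,,
NLGN1,p.L692M,,,,,
NLGN1,p.A695T,,,,,
NLGN1,p.Y698F,,,,,
NLGN1,p.Y698C,,,,,
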