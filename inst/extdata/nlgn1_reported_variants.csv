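gene,hgvs_p,significance,het,hom,hemi,sex
NLGN1,p.L25*,,,1,,
NLGN1,p.P89L,,1,,,
NLGN1,p.T90I,,1,,,
NLGN1,p.T90R,,1,,,
NLGN1,p.D140Y,,1,,,
NLGN1,p.I158K,,1,,,
NLGN1,p.L269P,,1,,,
NLGN1,p.T271fs,,1,,,
NLGN1,p.G297E,,1,,,
NLGN1,p.H795Y,,1,,,
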