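variant,box,e_complex,e_protein,e_dna
WT,ndh,-350.0,-200.0,-120.0
WT,PDC,-340.0,-200.0,-115.0
mPdhR,ndh,-330.0,-200.0,-120.0
mPdhR,PDC,-360.0,-200.0,-115.0
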