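id	class	anchor_ref	anchor_pos
Neuropaea_syn	AOB-HAO	TRUE	64
Nmobilis_syn	AOB-HAO	FALSE	NA
Kstuttgartiensis_syn	anammox-HAO	FALSE	NA
Cfetus_syn	epsilonHao	FALSE	NA
Ccurvus_syn	epsilonHao	FALSE	NA
Cmediatlanticus_syn	epsilonHao	FALSE	NA
Nprofundicola_syn	epsilonHao	FALSE	NA
NarLike1_syn	nitrate-reductase-like	FALSE	NA
NarLike2_syn	nitrate-reductase-like	FALSE	NA
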