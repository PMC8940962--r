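>Neuropaea_syn
TFALERTRWESTAVENLQFFFYCIDANMRISCVPFHCVDRVGGIYRCGLRTVTNEWLKCYKMMYESFCHVVFQFWELHLVPWSGDKMLHLAFYFKKMLLAWTQMGGFEWLTVVC
>Nmobilis_syn
TFALERTRIEQTMVGNMQFFFYCIDANMRISCKPFHCVITVGGHYDCGLRTVTNEWLKCYIMMYESFCHFVYQFMELHNVPWVGNKMLHLAPYFKKLLLANTEMYGREFLTDVC
>Kstuttgartiensis_syn
TIALEAQRIESTAHYNPYFFFYCIDAFGNISCALFHIYYTVGCHYDCLNRTVTGEWLKNYKFMYESMCHVVFQFCELANVWWLGNKMLIKALTHKPMLLCWTQMYGMEFLTEVC
>Cfetus_syn
TFMLEYTCHEFHMVRNKEFGFYCKDALYRL----FECRTMIGGQYPCRLCHAPDEMQKNYTMDWFQFCVTVSQIYEETLVPWSPNKMSIGIPPKKSMLQAGTAQRGRIGKTTSC
>Ccurvus_syn
TFMLMYTDHEFMMVRNKEFAFYCGDALDRL----FECRAMIGGQYDCRLCHAPDEMQKNYTMDWFQFDVTVFQIYEETLVPWSPNKMSIGAPPKKSLLSAGTGQRGRIGKYTPC
>Cmediatlanticus_syn
TFMLEYTCHEFHMVRNKEFAFYCGDALLRL----FECRAMIGGQYDCRLCHAPDEMWKNYTMDWFQFCVMVFQIAEETLVPWSPNKMSIGAPPKKSMLQAGTGQRMRIGKKTLC
>Nprofundicola_syn
TFMLNYTGHEFHMVRNKETAFPCGDALLRL----FECRAMIGGQYDCRLCYAPDEMQKNYTMDWFQFCVTVFQIYEETLVPWSPNKSSIGAPPKISMLDAGTGQRGRIGKTTLC
>NarLike1_syn
TFMLAYTCKETHMVRNKEFAYYKGFALLQL----FEDRAHIGGQYDGNYCHAMSHMVKNLTMDWCEFCVTVFQSYPEYLVPWSPNHMKIGAYPKKMMLQFGNGQVGRHGFTTVC
>NarLike2_syn
TFMLAYTCKEFHMVRNKEFAYYKGYILLRL----FEDRLMIGGQYDCRYDHAMSEMRKNPTMDWCEFCVTVFQVYPEYLVPWSPNHMKIGAYPKKMMLQNGNGQVWRCGHTTVC
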