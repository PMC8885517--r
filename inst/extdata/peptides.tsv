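sequence	protein
LTYYTPEYETK	RBCL
DLAVEGNEIIR	RBCL
AVYECLR	RBCL
DTDILAAFR	RBCL
ESTLGFVDLLR	RBCL
GGLDFTKDDENVNSQPFMR	RBCL
EVDEQMLNVQNK	TUB2
AVLVDLEPGTMDSVR	TUB2
FNTDQYCCR	PR5
GQTWVINAPR	PR5
LYIIQGDAYVMLPQYLK	ACT2
VAPEEHPVLLTEAPLNPK	ACT2
DAGTIAGLNVMR	HSP70
NAVVTVPAYFNDSQR	HSP70
TTPSYVAFTDTER	HSP70
FEELNMDLFR	HSP70
GVVDSDDLPLNVSR	HSP90
ELISNASDALDK	HSP90
ADLINNLGTIAK	HSP90
SIYYITGESK	HSP90
VGVTGEHGVVQPK	CAB1
FGEAVWFK	CAB1
NLAGDVIGTR	CAB1
SLNNNFLFEGK	GAPC1
VPTVDVSVVDLTVR	GAPC1
GILGYTEDDVVSTDFVGDNR	GAPC1
AASFNIIPSSTGAAK	GAPC1
IGINGFGR	GAPC1
YDSTLGIFDADVKPVGEDAIR	FBA1
ALQNTVLK	FBA1
TVVSIPNGPSELAVK	FBA1
AAQEEFIK	FBA1
LASINVENVETNR	PGK1
ELDYLVGAVSNPK	PGK1
GVSLLLPTDVVIADK	PGK1
FSLAPLVPR	SYNTH1
TGDVEYLNK	SYNTH2
AVDSLVPIGR	SYNTH3
YGVNDLDMAK	SYNTH4
LSSPATLNSR	SYNTH5
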