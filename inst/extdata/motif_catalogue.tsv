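name	pattern	note
zinc_clasp	Cx[CH]	CD4 cytoplasmic-tail Cx(C/H) clasp that binds the LCK CxxC through a zinc ion
itim_like	[FY]xxL[DE]	LAG-3 cytoplasmic-tail ITIM-like inhibitory motif
fxxl	FxxL	four-residue core of the ITIM-like motif, reported separately from the acidic fifth position
fpal_de	FPAL[DE]	frequent concrete form of the LAG-3 ITIM-like motif
canonical_itim	[IVL]xYxx[LV]	canonical ITIM consensus, found in some teleost LAG-3 tails
yxxm	YxxM	SH2-docking variant motif of zebrafish/channel catfish LAG-3
cd41_cterm	P[KQ]P[KR][AG]FY[HKR]	conserved C-terminal motif of ray-finned fish CD4-1 tails
wxc	WxC	unusual beta-strand-F signature of the D2 and D4 Ig-like domains
cxxc	CxxC	linker motif of reduced CD4-2 ectodomains; also the LCK clasp partner
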