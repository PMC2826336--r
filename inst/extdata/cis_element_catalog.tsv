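class	broad_category	iupac_pattern	tf_family	source
as1/ocs/TGA-like	as1/ocs/TGA-like	TGACGTCA	bZIP	TRANSFAC-style
ABRE-like	ABRE-like	YACGTGGC	bZIP	PLACE-style
DRE/CRT-like	DRE/CRT/rav1-like	TACCGACA	AP2/ERF	PLACE-style
rav1-like	DRE/CRT/rav1-like	CAACAGTC	AP2/ERF	TRANSFAC-style
GCC-box-like	GCC-box/JAre-like	GCCGCCGC	AP2/ERF	PLACE-style
JAre-like	GCC-box/JAre-like	AWTTCAAA	AP2/ERF	PLACE-style
MYB2-box-like	MYB2-box-like	TAACTGGC	MYB	PLACE-style
GARE-like	GARE/pyrimidine-box-like	TAACAAAC	MYB	PLACE-style
pyrimidine-box-like	GARE/pyrimidine-box-like	CCTTTTTC	MYB	PLACE-style
W-box-like	W-box-like	TTGACCAT	WRKY	PLACE-style
MYC2-box-like	MYC2-box-like	CACATGGC	bHLH	AGRIS-style
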