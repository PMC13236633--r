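gene_symbol	division	category
Col1a1	core matrisome	collagens
Col1a2	core matrisome	collagens
Col3a1	core matrisome	collagens
Col4a1	core matrisome	collagens
Col5a1	core matrisome	collagens
Col6a1	core matrisome	collagens
Col8a1	core matrisome	collagens
Col11a1	core matrisome	collagens
Col12a1	core matrisome	collagens
Col14a1	core matrisome	collagens
Fn1	core matrisome	ECM glycoproteins
Tnc	core matrisome	ECM glycoproteins
Postn	core matrisome	ECM glycoproteins
Tgfbi	core matrisome	ECM glycoproteins
Fbln2	core matrisome	ECM glycoproteins
Fbln5	core matrisome	ECM glycoproteins
Igfbp4	core matrisome	ECM glycoproteins
Dmbt1	core matrisome	ECM glycoproteins
Igsf10	core matrisome	ECM glycoproteins
Thbs3	core matrisome	ECM glycoproteins
Adamtsl1	core matrisome	ECM glycoproteins
Ltbp2	core matrisome	ECM glycoproteins
Thsd4	core matrisome	ECM glycoproteins
Eln	core matrisome	ECM glycoproteins
Nid1	core matrisome	ECM glycoproteins
Lama1	core matrisome	ECM glycoproteins
Lamb1	core matrisome	ECM glycoproteins
Sparc	core matrisome	ECM glycoproteins
Emilin1	core matrisome	ECM glycoproteins
Fbn1	core matrisome	ECM glycoproteins
Agrn	core matrisome	proteoglycans
Hspg2	core matrisome	proteoglycans
Dcn	core matrisome	proteoglycans
Bgn	core matrisome	proteoglycans
Lum	core matrisome	proteoglycans
Vcan	core matrisome	proteoglycans
Ogn	core matrisome	proteoglycans
Mmp2	matrisome-associated	ECM regulators
Mmp9	matrisome-associated	ECM regulators
P4ha1	matrisome-associated	ECM regulators
P4ha2	matrisome-associated	ECM regulators
Lox	matrisome-associated	ECM regulators
Loxl2	matrisome-associated	ECM regulators
Plat	matrisome-associated	ECM regulators
Serpinb2	matrisome-associated	ECM regulators
Serpinh1	matrisome-associated	ECM regulators
Tgm2	matrisome-associated	ECM regulators
Ctsb	matrisome-associated	ECM regulators
Plod1	matrisome-associated	ECM regulators
Itih2	matrisome-associated	ECM regulators
A2m	matrisome-associated	ECM regulators
Anxa1	matrisome-associated	ECM-affiliated proteins
Anxa2	matrisome-associated	ECM-affiliated proteins
Anxa5	matrisome-associated	ECM-affiliated proteins
Lgals1	matrisome-associated	ECM-affiliated proteins
Lgals3	matrisome-associated	ECM-affiliated proteins
S100a4	matrisome-associated	ECM-affiliated proteins
S100a6	matrisome-associated	ECM-affiliated proteins
S100a10	matrisome-associated	ECM-affiliated proteins
C1qa	matrisome-associated	ECM-affiliated proteins
Sema3a	matrisome-associated	ECM-affiliated proteins
Il1rn	matrisome-associated	secreted factors
Tgfb1	matrisome-associated	secreted factors
Vegfa	matrisome-associated	secreted factors
Wnt5a	matrisome-associated	secreted factors
Cxcl12	matrisome-associated	secreted factors
Igf1	matrisome-associated	secreted factors
Fgf2	matrisome-associated	secreted factors
Pdgfa	matrisome-associated	secreted factors
Angptl4	matrisome-associated	secreted factors
Ccl2	matrisome-associated	secreted factors
Hgf	matrisome-associated	secreted factors
S100a8	matrisome-associated	ECM-affiliated proteins
S100a9	matrisome-associated	ECM-affiliated proteins
Col15a1	core matrisome	collagens
Col18a1	core matrisome	collagens
Thbs1	core matrisome	ECM glycoproteins
Thbs2	core matrisome	ECM glycoproteins
Prelp	core matrisome	proteoglycans
Mmp3	matrisome-associated	ECM regulators
Timp1	matrisome-associated	ECM regulators
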