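# Mosaic Tol2 transgenic zebrafish assay outcomes for the putative
# arterial enhancers, transcribed from the published summary table.
# n_injected / n_gfp_positive: injected embryos / embryos with vascular
# GFP. Rows with NA counts were assayed only in earlier publications
# (cohort = published); the novel screen rows carry printed counts.
# weak_flag: GFP weak and/or limited to a small number of ECs.
# in_vivo_class: outcome of the transgenic screen.
# in_silico_class: label from relative enhancer/promoter marks in
# arterial vs venous human ECs.
name	n_injected	n_gfp_positive	weak_flag	in_vivo_class	in_silico_class	cohort
Cxcr4-232	163	0	FALSE	inactive	Uncalled	novel
Cxcr4-194	46	25	FALSE	arterial	Uncalled	novel
Cxcr4-130	95	0	FALSE	inactive	Uncalled	novel
Cxcr4-117	209	9	TRUE	inactive	Uncalled	novel
hCxcr4-117	81	0	FALSE	inactive	Uncalled	novel
Cxcr4-113	300	0	FALSE	inactive	Common EC enhancer	novel
Cxcr4-109	89	0	FALSE	inactive	Common EC enhancer	novel
Cxcr4+1	33	0	FALSE	inactive	Uncalled	novel
Cxcr4+119	187	0	FALSE	inactive	Arterial enhancer	novel
Cxcr4+135	69	56	FALSE	arterial	Uncalled	novel
Cxcr4+151	96	50	FALSE	arterial	Arterial TSS	novel
Efnb2-333	152	93	FALSE	arterial	Common EC enhancer	novel
Efnb2-159	247	217	FALSE	arterial	Common EC enhancer	novel
Efnb2-141	74	36	FALSE	arterial	Arterial TSS	novel
Efnb2-112	65	30	FALSE	arterial	Arterial TSS	novel
Efnb2+3	92	0	FALSE	inactive	Common EC TSS	novel
Efnb2+37	114	18	TRUE	weak	Common EC enhancer	novel
Efnb2+172	63	0	FALSE	inactive	Common EC enhancer	novel
Efnb2+209	158	0	FALSE	inactive	Common EC enhancer	novel
Gja4+24	52	0	FALSE	inactive	Uncalled	novel
Gja4+50	232	187	FALSE	arterial	Common EC enhancer	novel
Gja4+57	192	0	FALSE	inactive	Uncalled	novel
Unc5b-57	50	21	FALSE	venous	Uncalled	novel
Unc5b+14	61	0	FALSE	inactive	Uncalled	novel
Unc5b+23	82	16	TRUE	weak	Arterial enhancer	novel
Unc5b+30	96	79	FALSE	arterial	Arterial enhancer	novel
Unc5b+39	96	56	FALSE	arterial	Arterial enhancer	novel
Unc5b+43	111	0	FALSE	inactive	Arterial enhancer	novel
Acvrl1-5	NA	NA	FALSE	inactive	Common EC enhancer	published
Acvrl1-1/p	NA	NA	FALSE	inactive	Common EC TSS	published
Acvrl1+6	127	49	FALSE	arterial	Common EC TSS	novel
Acvrl1+16	205	0	FALSE	inactive	Common EC TSS	novel
Acvrl1+19	95	0	FALSE	inactive	Common EC TSS	novel
Cxcl12-184	64	0	FALSE	inactive	Common EC enhancer	novel
Cxcl12-2	32	0	FALSE	inactive	Common EC enhancer	novel
Cxcl12+239	70	1	FALSE	inactive	Uncalled	novel
Cxcl12+265	42	1	FALSE	inactive	Uncalled	novel
Cxcl12+269	163	63	FALSE	arterial	Uncalled	novel
Cxcl12+298	51	0	FALSE	inactive	Common EC enhancer	novel
Cxcl12+376	149	0	FALSE	inactive	Uncalled	novel
Cxcl12+383	152	37	TRUE	weak	Uncalled	novel
Cxcl12+439	73	0	FALSE	inactive	Common EC enhancer	novel
Cxcl12+445	145	0	FALSE	inactive	Common EC TSS	novel
Gja5-7	66	39	FALSE	arterial	Arterial enhancer	novel
Gja5-21	38	0	FALSE	inactive	Common EC enhancer	novel
Gja5-28	156	0	FALSE	inactive	Uncalled	novel
Gja5-78	76	62	FALSE	arterial	Common EC enhancer	novel
Gja5-93	253	0	FALSE	inactive	Arterial enhancer	novel
Nrp1+28	NA	NA	FALSE	pan_EC	Common EC enhancer	published
Nrp1+76	54	0	FALSE	inactive	Common EC enhancer	novel
Nrp1+78	191	34	FALSE	arterial	Common EC enhancer	novel
Nrp1+91	109	0	FALSE	inactive	Common EC enhancer	novel
Nrp1+129	110	0	FALSE	inactive	Common EC enhancer	novel
DLL4-12	NA	NA	FALSE	arterial	Common EC enhancer	published
DLL4in3	NA	NA	FALSE	arterial	Common EC enhancer	published
ECE1in1	NA	NA	FALSE	arterial	Common EC enhancer	published
Flk1in10	NA	NA	FALSE	arterial	Uncalled	published
Hey1-18	NA	NA	FALSE	arterial	Common EC enhancer	published
NOTCH1+16	NA	NA	FALSE	arterial	Common EC enhancer	published
Sema6d-55	NA	NA	FALSE	arterial	Common EC enhancer	published
SOX7+14	NA	NA	FALSE	arterial	Common EC enhancer	published
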