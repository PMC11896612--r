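# Enhancer-mark evidence at 32 known in vivo-characterized endothelial
# enhancers, transcribed from the published summary table.
# H_DNaseI: DNaseI hypersensitivity in human ECs (HUVEC, HMVEC-dBl);
# H_histone: H3K27Ac and/or H3K4Me1 enrichment in HUVECs;
# M_artery_ATAC: open chromatin in mouse adult aortic ECs;
# M_retina_ATAC: open chromatin in mouse P6 retina ECs;
# M_E11_p300: EP300 enrichment in mouse E11.5 endothelium.
# arterial: one of the eight previously published arterial enhancers.
# nonspecific_note: mark extends to many non-EC cell types.
name	H_DNaseI	H_histone	M_artery_ATAC	M_retina_ATAC	M_E11_p300	arterial	nonspecific_note
Apln+28	Yes	Yes	No	Yes	Yes	FALSE
Dab2-240	Yes	Yes	No	No	Yes	FALSE	H_DNaseI
Dll4in3	Yes	Yes	Yes	Yes	Yes	TRUE
Dll4-12	Yes	Yes	Yes	Yes	Yes	TRUE
Ece1in1	Yes	Yes	Yes	Yes	Yes	TRUE
Egfl7-9	Yes	Yes	Yes	Yes	Yes	FALSE
Egfl7-2	Yes	Yes	Yes	Yes	Yes	FALSE
Emcn-22	No	Yes	Yes	No	No	FALSE
Eng-8	Yes	Yes	Yes	Yes	Yes	FALSE
Eng+9	Yes	Yes	Yes	Yes	Yes	FALSE
Ephb4-2	Yes	Yes	No	No	Yes	FALSE
Fli1+12	Yes	Yes	Yes	Yes	Yes	FALSE
Flk1+3	Yes	Yes	No	No	Yes	FALSE
Flk1in10	Yes	No	No	Yes	Yes	TRUE
Flt4+26	No	Yes	Yes	Yes	Yes	FALSE
Foxp1+138	Yes	Yes	No	Yes	Yes	FALSE
Gata2+9	Yes	Yes	Yes	Yes	Yes	FALSE
Hey1-18	Yes	Yes	Yes	Yes	Yes	TRUE
Hlx-3	Yes	Yes	Yes	Yes	Yes	FALSE
Mef2F10	Yes	Yes	No	Yes	Yes	FALSE
Mef2F7	Yes	Yes	Yes	Yes	Yes	FALSE
Notch1+16	Yes	Yes	Yes	Yes	Yes	TRUE
Notch1+33	Yes	Yes	Yes	Yes	Yes	FALSE
CoupTFII-965	Yes	Yes	Yes	Yes	Yes	FALSE
Nrp1+28	No	Yes	Yes	Yes	Yes	FALSE
Nrp2+26	Yes	Yes	Yes	Yes	Yes	FALSE
Pdgfrb+18	No	Yes	No	No	No	FALSE
Epcr-5	Yes	Yes	Yes	No	Yes	FALSE
Sema6d-55	Yes	Yes	Yes	Yes	Yes	TRUE
Sox7+14	Yes	Yes	Yes	Yes	Yes	TRUE
Tal+19	Yes	Yes	Yes	Yes	Yes	FALSE
Tal1-4	No	Yes	Yes	Yes	Yes	FALSE
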