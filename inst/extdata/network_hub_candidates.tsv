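protein_id	degree	tail_p	rescued	seed	correlating	dyrk1a_target
Rps27a	43	0.010	no	no	no	no
Uba52	40	0.012	no	no	no	no
Trp53	38	0.013	no	no	no	yes
Ubc	38	0.013	no	no	no	no
Rac1	34	0.017	no	no	no	no
Smad3	28	0.025	yes	yes	no	no
Prnp	25	0.031	yes	yes	no	no
Hras	24	0.034	yes	yes	no	yes
Pten	22	0.040	yes	yes	no	no
Grb2	22	0.040	no	no	no	yes
Med16	18	0.058	no	yes	no	no
Rela	17	0.064	no	no	no	no
Pik3r1	17	0.064	no	no	no	no
Hsp90ab1	16	0.071	no	yes	yes	no
Arhgef7	16	0.071	yes	yes	no	no
Ripk1	15	0.079	yes	yes	no	no
Smad4	15	0.079	no	no	no	no
Pik3ca	15	0.079	no	no	no	no
Irs2	14	0.088	no	yes	no	no
Hdac1	14	0.088	no	no	no	no
Ubb	13	0.099	no	no	no	no
Dvl1	13	0.099	no	no	no	no
Pik3cb	13	0.099	no	no	no	no
Axin1	13	0.099	no	no	no	no
Pip5k1c	13	0.099	yes	yes	no	no
Bcl2	13	0.099	no	no	no	no
Raf1	12	0.113	no	no	no	no
Smurf2	12	0.113	no	no	no	no
Casp3	12	0.113	no	no	no	no
Mdm2	11	0.128	no	no	no	no
Ralbp1	11	0.128	yes	yes	no	no
Pdgfrb	11	0.128	no	no	no	no
Pik3cd	11	0.128	no	no	no	no
Psmd4	11	0.128	no	no	no	no
Itsn1	11	0.128	no	no	no	no
Cav1	10	0.147	no	yes	no	no
Pik3cg	10	0.147	no	no	no	no
Gja1	10	0.147	yes	yes	no	no
Hsph1	10	0.147	yes	yes	yes	no
Nck2	10	0.147	yes	yes	no	no
Prkcd	10	0.147	no	yes	no	no
Synj1	10	0.147	yes	yes	yes	yes
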