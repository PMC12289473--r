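patient_id	cdna	protein	exon	variant_type	zygosity	criteria	classification
P1	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P1	c.1092dupC	p.(Phe365LeufsTer78)	Exon 6	Frameshift	het	PVS1+PM2	Likely pathogenic
P2	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P2	c.1370T>G	p.(Leu457Arg)	Exon 8	Missense	het	PM2+PP3+PS3	Likely pathogenic
P3	c.1673del	p.(Gly558AlafsTer65)	Exon 11	Nonsense	hom	PM2	VUS
P4	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P4	c.942+1G>A	IVS4+1G>A	Intron 4	Noncoding	het	PVS1+PP5+PM2	Pathogenic
P5	c.1640_1641del	p.(Pro547GlnfsTer235)	Exon 11	Frameshift	het	PVS1+PM2	Likely pathogenic
P5	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P6	c.1640_1641del	p.(Pro547GlnfsTer235)	Exon 10	Frameshift	het	PVS1+PM2	Likely pathogenic
P6	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P7	c.1130_1168del	p.(Ala377_Ser389del)	Exon 6	In-frame	het	PM4+PM2	VUS
P7	c.1345G>C	p.(Gly449Arg)	Exon 8	Missense	het	PM3+PM2+PP3	Likely pathogenic
P8	c.49G>A	p.(Gly17Arg)	Exon 2	Missense	het	PM2+PP3	VUS
P8	c.942+1G>A	IVS4+1G>A	Intron 4	Noncoding	het	PVS1+PP5+PM2	Pathogenic
P9	c.1732del	p.(Asp578ThrfsTer45)	Exon 11	Frameshift	hom	PVS1+PM2	Likely pathogenic
P10	c.690-2A>G	.	Intron 2	Noncoding	hom	PM3+PVS1+PM2	Pathogenic
P11	c.619C>T	p.(Arg207Ter)	Exon 2	Nonsense	hom	PM3+PVS1+PM2	Pathogenic
P12	c.968_969del	p.(Leu323ProfsTer119)	Exon 5	Frameshift	het	PM3+PVS1+PM2	Pathogenic
P12	c.1199_1201del	p.(Tyr400del)	Exon 6	In-frame	het	PP5+PM4+PM2	Pathogenic
P13	c.1631dupA	p.(Tyr544fsTer79)	Exon 11	Nonsense	hom	PVS1+PM2	Likely pathogenic
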