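patient_id	Prenatal_complications	Neonatal_complications	Hypotonia	Developmental_delay	Epilepsy	Abnormal_movements	Facial_dysmorphism	Cardiac	Genitourinary	Ocular	Skeletal	Teeth	GIT_issues	MRI_findings	Increased_serum_ALP	HyperCKemia_rhabdomyolysis
P1	+	+	+	+	+	+	+	+	-	+	+	+	-	+	+	+
P2	+	+	+	+	+	+	+	-	-	+	+	+	+	+	n.a.	-
P3	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	n.a.
P4	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	n.a.
P5	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	n.a.
P6	-	+	+	+	+	+	+	+	+	+	+	-	+	+	+	n.a.
P7	-	+	+	+	+	+	+	+	+	+	+	-	+	+	-	n.a.
P8	-	+	+	+	+	+	+	+	+	+	+	-	+	+	-	n.a.
P9	-	+	+	+	+	+	+	+	+	+	+	-	+	+	-	n.a.
P10	-	-	+	+	+	+	+	-	-	+	-	-	+	n.a.	n.a.	n.a.
P11	-	-	+	+	+	-	+	-	-	+	-	n.a.	n.a.	n.a.	n.a.	n.a.
P12	-	-	n.a.	+	n.a.	n.a.	+	-	n.a.	+	-	n.a.	n.a.	n.a.	n.a.	n.a.
P13	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.	n.a.
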