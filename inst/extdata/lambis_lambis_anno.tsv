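# organism=Lambis lambis
# genome_length=15481
# circular=true
gene	class	start	end	strand	start_codon	stop_codon	size_nt	size_aa	intergenic
cox1	PCG	1	1536	+	ATG	TAA	1536	511	4
cox2	PCG	1556	2242	+	ATG	TAA	687	228	19
trnD	tRNA	2241	2308	+	NA	NA	68	NA	-2
atp8	PCG	2309	2467	+	ATG	TAA	159	52	0
atp6	PCG	2472	3167	+	ATG	TAA	696	232	4
trnM	tRNA	3204	3271	-	NA	NA	68	NA	36
trnY	tRNA	3290	3355	-	NA	NA	66	NA	18
trnC	tRNA	3358	3422	-	NA	NA	65	NA	2
trnW	tRNA	3424	3490	-	NA	NA	67	NA	1
trnQ	tRNA	3492	3553	-	NA	NA	62	NA	1
trnG	tRNA	3566	3632	-	NA	NA	67	NA	12
trnE	tRNA	3634	3703	-	NA	NA	70	NA	1
rrnS	rRNA	3708	4693	+	NA	NA	986	NA	4
trnV	tRNA	4694	4760	+	NA	NA	67	NA	0
rrnL	rRNA	4753	6147	+	NA	NA	1395	NA	-8
trnL1	tRNA	6150	6218	+	NA	NA	69	NA	2
trnL2	tRNA	6226	6294	+	NA	NA	69	NA	7
nad1	PCG	6296	7237	+	ATG	TAG	942	313	1
trnP	tRNA	7247	7315	+	NA	NA	69	NA	9
nad6	PCG	7320	7826	+	ATG	TAA	507	168	4
cytb	PCG	7836	8975	+	ATG	TAA	1140	379	9
trnS2	tRNA	8990	9055	+	NA	NA	66	NA	14
trnT	tRNA	9076	9141	-	NA	NA	66	NA	20
nad4l	PCG	9150	9446	+	ATG	TAG	297	98	8
nad4	PCG	9440	10813	+	ATG	TAA	1374	457	-7
trnH	tRNA	10818	10884	+	NA	NA	67	NA	4
nad5	PCG	10885	12612	+	ATG	TAA	1728	575	0
trnF	tRNA	12654	12725	+	NA	NA	72	NA	41
cox3	PCG	12780	13559	+	ATG	TAA	780	259	54
trnK	tRNA	13597	13666	+	NA	NA	70	NA	37
trnA	tRNA	13693	13763	+	NA	NA	71	NA	26
trnR	tRNA	13774	13842	+	NA	NA	69	NA	10
trnN	tRNA	13854	13923	+	NA	NA	70	NA	11
trnI	tRNA	13925	13992	+	NA	NA	68	NA	1
nad3	PCG	13994	14347	+	ATG	TAA	354	117	1
trnS1	tRNA	14351	14418	+	NA	NA	68	NA	3
nad2	PCG	14407	15477	+	ATC	TAG	1071	356	-12
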