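# organism=Harpago chiragra
# genome_length=15460
# circular=true
gene	class	start	end	strand	start_codon	stop_codon	size_nt	size_aa	intergenic
cox1	PCG	1	1536	+	ATG	TAG	1536	511	5
cox2	PCG	1556	2242	+	ATG	TAA	687	228	19
trnD	tRNA	2241	2308	+	NA	NA	68	NA	-2
atp8	PCG	2309	2467	+	ATG	TAA	159	52	0
atp6	PCG	2470	3165	+	ATG	TAA	696	231	2
trnM	tRNA	3202	3269	-	NA	NA	68	NA	36
trnY	tRNA	3288	3353	-	NA	NA	66	NA	18
trnC	tRNA	3356	3420	-	NA	NA	65	NA	2
trnW	tRNA	3422	3488	-	NA	NA	67	NA	1
trnQ	tRNA	3490	3551	-	NA	NA	62	NA	1
trnG	tRNA	3564	3630	-	NA	NA	67	NA	12
trnE	tRNA	3632	3701	-	NA	NA	70	NA	1
rrnS	rRNA	3707	4684	+	NA	NA	978	NA	5
trnV	tRNA	4685	4751	+	NA	NA	67	NA	0
rrnL	rRNA	4737	6127	+	NA	NA	1391	NA	-15
trnL1	tRNA	6134	6202	+	NA	NA	69	NA	6
trnL2	tRNA	6212	6280	+	NA	NA	69	NA	9
nad1	PCG	6282	7223	+	ATG	TAG	942	313	1
trnP	tRNA	7234	7301	+	NA	NA	68	NA	10
nad6	PCG	7303	7809	+	ATG	TAA	507	168	1
cytb	PCG	7821	8960	+	ATG	TAA	1140	379	11
trnS2	tRNA	8975	9040	+	NA	NA	66	NA	14
trnT	tRNA	9059	9125	-	NA	NA	67	NA	18
nad4l	PCG	9135	9431	+	ATG	TAG	297	98	9
nad4	PCG	9425	10798	+	GTG	TAA	1374	457	-7
trnH	tRNA	10808	10874	+	NA	NA	67	NA	9
nad5	PCG	10875	12602	+	ATG	TAA	1728	575	0
trnF	tRNA	12634	12702	+	NA	NA	69	NA	31
cox3	PCG	12756	13535	+	ATG	TAA	780	259	53
trnK	tRNA	13574	13643	+	NA	NA	70	NA	38
trnA	tRNA	13671	13742	+	NA	NA	72	NA	27
trnR	tRNA	13754	13822	+	NA	NA	69	NA	11
trnN	tRNA	13835	13901	+	NA	NA	67	NA	12
trnI	tRNA	13904	13971	+	NA	NA	68	NA	2
nad3	PCG	13973	14326	+	ATG	TAA	354	117	1
trnS1	tRNA	14329	14396	+	NA	NA	68	NA	2
nad2	PCG	14385	15455	+	ATC	TAG	1071	356	-12
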