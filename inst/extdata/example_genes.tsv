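genome_id	contig	ordinal	gene_id	strand	label
genomeA	chr	1	gA_g001	+
genomeA	chr	2	gA_g002	-
genomeA	chr	3	gA_g003	+	dehydratase_46
genomeA	chr	4	gA_g004	+
genomeA	chr	5	gA_g005	+	epimerase_35
genomeA	chr	6	gA_g006	-
genomeA	chr	7	gA_g007	+	reductase_4
genomeA	chr	8	gA_g008	+
genomeA	chr	9	gA_g009	-
genomeA	chr	10	gA_g010	+
genomeA	chr	11	gA_g011	+
genomeA	chr	12	gA_g012	-
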