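##fileformat=VCFv4.2
##contig=<ID=CamParChr2,length=75000000>
##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the structural variant">
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##ALT=<ID=DEL,Description="Deletion">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DV,Number=1,Type=Integer,Description="Supporting split-read count">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	bird1	bird2
CamParChr2	10000	DEL001	N	<DEL>	.	PASS	SVTYPE=DEL;END=10500	GT:DV	0/1:7	1/1:12
CamParChr2	20000	DEL002	N	<DEL>	.	PASS	SVTYPE=DEL;END=20190	GT:DV	0/0:0	0/1:4
CamParChr2	30000	DEL003	N	<DEL>	.	PASS	SVTYPE=DEL;END=80000	GT:DV	1/1:9	0/0:0
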