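##fileformat=VCFv4.2
##source=hand-written toy fixture
##contig=<ID=ctg1,length=2000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
ctg1	100	.	A	T	.	.	.	GT:AD:DP	0/1:3,4:7
ctg1	200	.	C	G	.	.	.	GT:AD:DP	0/1:9,1:10
ctg1	300	.	G	A	.	.	.	GT:AD:DP	0/1:95,5:100
ctg1	400	.	T	C	.	.	.	GT:AD:DP	0/1:20,20:40
ctg1	500	.	A	G	.	.	.	GT:AD:DP	0/1:20,10:30
ctg1	600	.	C	T	.	.	.	GT:AD:DP	0/1:48,2:50
ctg1	700	.	G	T,C	.	.	.	GT:AD:DP	0/1/2:18,10,2:30
ctg1	800	.	A	C	.	.	.	GT:AD:DP	0/1:7,1:8
ctg1	900	.	A	ATG	.	.	.	GT:AD:DP	0/1:15,5:20
ctg1	1000	.	ACG	A	.	.	.	GT:AD:DP	0/1:16,4:20
ctg1	1100	.	T	A	.	.	.	GT:AD:DP	./.:.:.
ctg1	1200	.	G	C	.	.	.	GT:AD:DP	0/1:19,1:20
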