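##fileformat=VCFv4.2
##contig=<ID=chrS,length=120>
##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Variant origin">
##INFO=<ID=EFFECT,Number=1,Type=String,Description="Annotated effect">
##INFO=<ID=CLASS,Number=1,Type=String,Description="Locus class">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NORMAL	TUMOR
chrS	10	chrS:10	C	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	70,30
chrS	20	chrS:20	A	C	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	75,25
chrS	30	chrS:30	T	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	60,40
chrS	40	chrS:40	T	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	95,5
chrS	50	chrS:50	A	C	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	96,4
chrS	60	chrS:60	T	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	98,2
chrS	70	chrS:70	T	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	65,35
chrS	80	chrS:80	C	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	80,20
chrS	90	chrS:90	A	C	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	55,45
chrS	100	chrS:100	T	A	.	PASS	ORIGIN=SOMATIC;EFFECT=noncoding;CLASS=somatic	AD	100,0	72,28
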