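category	unique_c1	unique_t1	unique_c2	unique_t2	reads_c1	reads_t1	reads_c2	reads_t2
rRNA	112291	126346	133724	147784	1995335	2054201	2095372	2517033
tRNA	37394	37971	35593	45462	3764841	2166029	4133757	2557011
snoRNA	17488	20634	18452	24474	850682	893967	295169	141849
snRNA	9485	11277	10164	13596	60773	64856	47312	59258
miRNA	1451	1697	1615	2056	109924	268389	80626	407419
other	50142	55613	54114	70463	554968	449981	673621	544438
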