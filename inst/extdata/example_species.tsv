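# Example expert (blind) parameter table for a small northern hardwood
# understory community. Niche parameters are given as class ranks and
# resolved to physical units through the class key (see default_class_key
# or extdata/class_key.yaml).
name	ph_class	n_class	moisture_class	light_class	tmin	tmax	rooting_class	shading_class
Dryopteris intermedia	2	1	3	1	2	28	2	3
Viburnum acerifolium	2	1	3	2	2	30	3	5
Huperzia lucidula	2	1	4	1	0	26	1	1
Fagus grandifolia	2	2	3	2	2	30	4	5
Uvularia sessilifolia	3	2	3	2	2	28	2	2
Clintonia borealis	2	1	4	1	0	26	2	2
Maianthemum canadense	2	1	3	1	0	28	1	1
Oxalis montana	2	1	4	1	0	24	1	1
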