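sample_id	group	ph	phylotype	count
acid_s1	acid_site	3.6	Rhz1	14
acid_s1	acid_site	3.6	Aca1	11
acid_s2	acid_site	3.9	Rhz1	20
acid_s2	acid_site	3.9	Glo2	5
mid_s1	mid_site	5.4	Rhz1	6
mid_s1	mid_site	5.4	Glo1	12
mid_s1	mid_site	5.4	Aca1	7
mid_s2	mid_site	5.7	Glo1	15
mid_s2	mid_site	5.7	Rhz1	10
neutral_s1	neutral_site	6.9	Glo1	9
neutral_s1	neutral_site	6.9	Scu1	8
neutral_s1	neutral_site	6.9	Rhz1	8
neutral_s2	neutral_site	7.1	Scu1	13
neutral_s2	neutral_site	7.1	Glo1	12
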