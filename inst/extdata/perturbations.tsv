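experiment	gene_class	model	context	k1	k_minus1	k2	k_minus2	k3	k_minus3	k4	k5	k6_speed	k7
Sua7 degradation	STM	1	standard			0.004-0.04							
Sua7 degradation	STM	2	standard		0.04	0.004-0.04							
Sua7 degradation	STM	3	standard	0.0006		0.004-0.04							
Sua7 degradation	TFO	1	standard					0.0008					
Sua7 degradation	TFO	2	standard					0.0008	0.0-0.12				
Kin28 inhibition	STM	1	standard								0.02		
Kin28 inhibition	STM	2	standard						0.0-0.24		0.02		
Kin28 inhibition	STM	3	standard		0.06						0.02		
Kin28 inhibition	STM	4	standard	0.0005							0.02		
Kin28 inhibition	TFO	1	standard								0.02		
Kin28 inhibition	TFO	2	standard						0.0-0.24		0.02		
Kin28 inhibition	TFO	3	standard					0.0005			0.02		
gcn4-pd	STM	1	gcn4						0.0-0.048				
gcn4-pd	STM	2	gcn4			0.0092-0.092			0.0-0.045				
gcn4-null	STM	1	gcn4	0.0006									
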