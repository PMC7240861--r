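pathway	set_id	input_number	background_number	p_value	corrected_p	genes
Cardiac conduction	R-HSA-5576891	3	141	0.0246	0.177	HIPK2;NOS1;ASPH
Ion homeostasis	R-HSA-5578775	2	56	0.026	0.179	NOS1;ASPH
Axon guidance	R-HSA-422475	6	549	0.034	0.191	COL4A3;EPHB4;PSMB11;COL5A1;EVL;ROBO1
Ion channel transport	R-HSA-983712	3	211	0.066	0.229	SLC9B1;ATP2C2;ASPH
SLAM protein interactions at the synapses	R-HSA-8849932	1	21	0.091	0.261	LRFN4
Ion transport by P-type ATPases	R-HSA-936837	1	57	0.222	0.379	ATP2C2
Transport of inorganic cations/anions and amino acids/oligopeptides	R-HSA-425393	1	100	0.354	0.486	SLC26A4
Neuronal System	R-HSA-112316	1	339	0.771	0.800	LRFN4
Vesicle-mediated transport	R-HSA-5653656	1	573	0.918	0.9236	CD163
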