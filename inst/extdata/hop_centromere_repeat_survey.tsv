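repeat	monomer_length	chip_hits	input_hits	normalized_ratio	annotation
SaazCEN	284	89401	6006	31.0	satellite
Saaz293	323	206894	6777	63.6	satellite
Saaz85	320	22376	137676	0.34	satellite
Saaz40	324	42832	906	98.5	satellite
HuluTR120	120	402834	36562	23.0	satellite
SaazCRM1	variable	713546	37509	39.6	Ty3/Gypsy_CRM
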