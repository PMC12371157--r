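# Synthetic primer-binding-site motif catalog (PBS1-PBS4).
# tRNA-complementary-like 14-mers (leading TGG complements the universal
# tRNA 3'-CCA); sequences are stand-ins, ids mirror the four dominant
# motif groups of CRM-like retroelements.
PBS1	TGGTATCAGAGCCA
PBS2	TGGCGCCCAACTTG
PBS3	TGGTACCGGATCGA
PBS4	TGGCACCAGTTCAA
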