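node_label,taxonA,taxonB
node2,O_ornatus,B_warddi
node3,G_cirratum,N_ferrugineus
node4,G_cirratum,R_typus
node5,S_tigrinum,R_typus
node6,G_cirratum,H_ocellatum
node7,C_griseum,H_ocellatum
root,P_collare,G_cirratum
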