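(P_collare:200,((B_warddi:150,(O_ornatus:30,(O_maculatus:18,O_halei:18):12):120):35,((C_griseum:60,(C_plagiosum:35,H_ocellatum:35):25):80,(((G_cirratum:8,G_unami:8):32,N_ferrugineus:40):70,((S_tigrinum:50,P_brevicaudatum:50):25,R_typus:75):35):30):45):15);
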