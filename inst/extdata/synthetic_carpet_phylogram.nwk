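(P_collare:0.712423,((B_warddi:0.478318,(O_ornatus:0.085626,(O_maculatus:0.051464,O_halei:0.070658):0.043656):0.369756):0.107182,((C_griseum:0.245195,(C_plagiosum:0.097343,H_ocellatum:0.09949):0.058866):0.282158,(((G_cirratum:0.016088,G_unami:0.02828):0.062301,N_ferrugineus:0.110785):0.194526,((S_tigrinum:0.173979,P_brevicaudatum:0.192677):0.070654,R_typus:0.2039):0.077701):0.095708):0.129278):0.039967);
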