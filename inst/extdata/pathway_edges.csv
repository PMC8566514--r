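from,to,reaction,reaction_class
Cyantraniliprole,IN-J9Z38,ring_closure,functionalization
IN-J9Z38,IN-MLA84,N_demethylation,functionalization
IN-J9Z38,TP633,glycosylation,conjugation
IN-MLA84,TP619,glycosylation,conjugation
IN-J9Z38,IN-RNU71,dechlorination_hydroxylation,functionalization
IN-MLA84,TP423,dechlorination_hydroxylation,functionalization
IN-MLA84,TP363,debromination,functionalization
IN-MLA84,TP405,dechlorination,functionalization
IN-MLA84,TP441,isomerization,functionalization
IN-J9Z38,TP577,cyano_oxidation_cysteine_conjugation,conjugation
Cyantraniliprole,IN-MYX98,N_methyl_hydroxylation,functionalization
IN-MYX98,TP651a,glycosylation,conjugation
IN-MYX98,TP651b,glycosylation,conjugation
IN-MYX98,IN-HGW87,N_dealkylation,functionalization
Cyantraniliprole,IN-JCZ38,cyano_hydration,functionalization
IN-JCZ38,IN-JSE76,amide_hydrolysis,functionalization
IN-JSE76,TP654,glucose_conjugation,conjugation
Cyantraniliprole,IN-DBC80,carboxamide_bridge_cleavage,cleavage
Cyantraniliprole,IN-M2G98,carboxamide_bridge_cleavage,cleavage
Cyantraniliprole,TP315,carboxamide_bridge_cleavage,cleavage
Cyantraniliprole,TP316,carboxamide_bridge_cleavage,cleavage
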