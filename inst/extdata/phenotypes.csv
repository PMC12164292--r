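species,limb,digit,phalanx_min,phalanx_max,claw,present,provisional
ancestor,forelimb,I,2,2,TRUE,TRUE,FALSE
ancestor,forelimb,II,3,3,TRUE,TRUE,FALSE
ancestor,forelimb,III,4,4,TRUE,TRUE,FALSE
ancestor,forelimb,IV,5,5,TRUE,TRUE,FALSE
ancestor,forelimb,V,3,3,TRUE,TRUE,FALSE
ancestor,hindlimb,I,2,2,TRUE,TRUE,FALSE
ancestor,hindlimb,II,3,3,TRUE,TRUE,FALSE
ancestor,hindlimb,III,4,4,TRUE,TRUE,FALSE
ancestor,hindlimb,IV,5,5,TRUE,TRUE,FALSE
ancestor,hindlimb,V,4,4,TRUE,TRUE,FALSE
bearded_dragon,forelimb,I,2,2,TRUE,TRUE,FALSE
bearded_dragon,forelimb,II,3,3,TRUE,TRUE,FALSE
bearded_dragon,forelimb,III,4,4,TRUE,TRUE,FALSE
bearded_dragon,forelimb,IV,5,5,TRUE,TRUE,FALSE
bearded_dragon,forelimb,V,3,3,TRUE,TRUE,FALSE
bearded_dragon,hindlimb,I,2,2,TRUE,TRUE,FALSE
bearded_dragon,hindlimb,II,3,3,TRUE,TRUE,FALSE
bearded_dragon,hindlimb,III,4,4,TRUE,TRUE,FALSE
bearded_dragon,hindlimb,IV,5,5,TRUE,TRUE,FALSE
bearded_dragon,hindlimb,V,4,4,TRUE,TRUE,FALSE
tokay_gecko,forelimb,I,2,2,TRUE,TRUE,FALSE
tokay_gecko,forelimb,II,3,3,TRUE,TRUE,FALSE
tokay_gecko,forelimb,III,4,4,TRUE,TRUE,FALSE
tokay_gecko,forelimb,IV,5,5,TRUE,TRUE,FALSE
tokay_gecko,forelimb,V,3,3,TRUE,TRUE,FALSE
tokay_gecko,hindlimb,I,2,2,TRUE,TRUE,FALSE
tokay_gecko,hindlimb,II,3,3,TRUE,TRUE,FALSE
tokay_gecko,hindlimb,III,4,4,TRUE,TRUE,FALSE
tokay_gecko,hindlimb,IV,5,5,TRUE,TRUE,FALSE
tokay_gecko,hindlimb,V,4,4,TRUE,TRUE,FALSE
mouse,forelimb,I,2,2,TRUE,TRUE,FALSE
mouse,forelimb,II,3,3,TRUE,TRUE,FALSE
mouse,forelimb,III,3,3,TRUE,TRUE,FALSE
mouse,forelimb,IV,3,3,TRUE,TRUE,FALSE
mouse,forelimb,V,3,3,TRUE,TRUE,FALSE
mouse,hindlimb,I,2,2,TRUE,TRUE,FALSE
mouse,hindlimb,II,3,3,TRUE,TRUE,FALSE
mouse,hindlimb,III,3,3,TRUE,TRUE,FALSE
mouse,hindlimb,IV,3,3,TRUE,TRUE,FALSE
mouse,hindlimb,V,3,3,TRUE,TRUE,FALSE
chinese_softshell_turtle,forelimb,I,2,2,TRUE,TRUE,FALSE
chinese_softshell_turtle,forelimb,II,3,3,TRUE,TRUE,FALSE
chinese_softshell_turtle,forelimb,III,3,3,TRUE,TRUE,FALSE
chinese_softshell_turtle,forelimb,IV,3,6,FALSE,TRUE,FALSE
chinese_softshell_turtle,forelimb,V,2,5,FALSE,TRUE,FALSE
chinese_softshell_turtle,hindlimb,I,2,2,TRUE,TRUE,FALSE
chinese_softshell_turtle,hindlimb,II,3,3,TRUE,TRUE,FALSE
chinese_softshell_turtle,hindlimb,III,3,3,TRUE,TRUE,FALSE
chinese_softshell_turtle,hindlimb,IV,3,6,FALSE,TRUE,FALSE
chinese_softshell_turtle,hindlimb,V,2,5,FALSE,TRUE,FALSE
broad_snouted_caiman,forelimb,I,2,2,TRUE,TRUE,FALSE
broad_snouted_caiman,forelimb,II,3,3,TRUE,TRUE,FALSE
broad_snouted_caiman,forelimb,III,4,4,TRUE,TRUE,FALSE
broad_snouted_caiman,forelimb,IV,5,5,FALSE,TRUE,FALSE
broad_snouted_caiman,forelimb,V,3,3,FALSE,TRUE,FALSE
broad_snouted_caiman,hindlimb,I,2,2,TRUE,TRUE,FALSE
broad_snouted_caiman,hindlimb,II,3,3,TRUE,TRUE,FALSE
broad_snouted_caiman,hindlimb,III,4,4,TRUE,TRUE,FALSE
broad_snouted_caiman,hindlimb,IV,5,5,FALSE,TRUE,FALSE
broad_snouted_caiman,hindlimb,V,0,0,FALSE,FALSE,FALSE
dwarf_crocodile,forelimb,I,2,2,TRUE,TRUE,FALSE
dwarf_crocodile,forelimb,II,3,3,TRUE,TRUE,FALSE
dwarf_crocodile,forelimb,III,4,4,TRUE,TRUE,FALSE
dwarf_crocodile,forelimb,IV,5,5,FALSE,TRUE,FALSE
dwarf_crocodile,forelimb,V,3,3,FALSE,TRUE,FALSE
dwarf_crocodile,hindlimb,I,2,2,TRUE,TRUE,FALSE
dwarf_crocodile,hindlimb,II,3,3,TRUE,TRUE,FALSE
dwarf_crocodile,hindlimb,III,4,4,TRUE,TRUE,FALSE
dwarf_crocodile,hindlimb,IV,5,5,FALSE,TRUE,FALSE
dwarf_crocodile,hindlimb,V,0,0,FALSE,FALSE,FALSE
nile_crocodile,forelimb,I,2,2,TRUE,TRUE,FALSE
nile_crocodile,forelimb,II,3,3,TRUE,TRUE,FALSE
nile_crocodile,forelimb,III,4,4,TRUE,TRUE,FALSE
nile_crocodile,forelimb,IV,5,5,FALSE,TRUE,FALSE
nile_crocodile,forelimb,V,3,3,FALSE,TRUE,FALSE
nile_crocodile,hindlimb,I,2,2,TRUE,TRUE,FALSE
nile_crocodile,hindlimb,II,3,3,TRUE,TRUE,FALSE
nile_crocodile,hindlimb,III,4,4,TRUE,TRUE,FALSE
nile_crocodile,hindlimb,IV,5,5,FALSE,TRUE,FALSE
nile_crocodile,hindlimb,V,0,0,FALSE,FALSE,FALSE
greater_rhea,forelimb,I,0,0,FALSE,FALSE,FALSE
greater_rhea,forelimb,II,2,2,TRUE,TRUE,FALSE
greater_rhea,forelimb,III,2,2,FALSE,TRUE,FALSE
greater_rhea,forelimb,IV,1,1,FALSE,TRUE,TRUE
greater_rhea,forelimb,V,0,0,FALSE,FALSE,FALSE
greater_rhea,hindlimb,I,0,0,FALSE,FALSE,FALSE
greater_rhea,hindlimb,II,3,3,TRUE,TRUE,FALSE
greater_rhea,hindlimb,III,4,4,TRUE,TRUE,FALSE
greater_rhea,hindlimb,IV,5,5,TRUE,TRUE,FALSE
greater_rhea,hindlimb,V,0,0,FALSE,FALSE,FALSE
duck,forelimb,I,0,0,FALSE,FALSE,FALSE
duck,forelimb,II,2,2,TRUE,TRUE,FALSE
duck,forelimb,III,3,3,TRUE,TRUE,FALSE
duck,forelimb,IV,2,2,FALSE,TRUE,FALSE
duck,forelimb,V,0,0,FALSE,FALSE,FALSE
duck,hindlimb,I,2,2,TRUE,TRUE,FALSE
duck,hindlimb,II,3,3,TRUE,TRUE,FALSE
duck,hindlimb,III,4,4,TRUE,TRUE,FALSE
duck,hindlimb,IV,5,5,TRUE,TRUE,FALSE
duck,hindlimb,V,0,0,FALSE,FALSE,FALSE
chicken,forelimb,I,0,0,FALSE,FALSE,FALSE
chicken,forelimb,II,2,2,TRUE,TRUE,FALSE
chicken,forelimb,III,2,2,FALSE,TRUE,FALSE
chicken,forelimb,IV,2,2,FALSE,TRUE,FALSE
chicken,forelimb,V,0,0,FALSE,FALSE,FALSE
chicken,hindlimb,I,2,2,TRUE,TRUE,FALSE
chicken,hindlimb,II,3,3,TRUE,TRUE,FALSE
chicken,hindlimb,III,4,4,TRUE,TRUE,FALSE
chicken,hindlimb,IV,5,5,TRUE,TRUE,FALSE
chicken,hindlimb,V,0,0,FALSE,FALSE,FALSE
zebra_finch,forelimb,I,0,0,FALSE,FALSE,FALSE
zebra_finch,forelimb,II,1,1,FALSE,TRUE,TRUE
zebra_finch,forelimb,III,2,2,FALSE,TRUE,TRUE
zebra_finch,forelimb,IV,1,1,FALSE,TRUE,TRUE
zebra_finch,forelimb,V,0,0,FALSE,FALSE,FALSE
zebra_finch,hindlimb,I,2,2,TRUE,TRUE,FALSE
zebra_finch,hindlimb,II,3,3,TRUE,TRUE,FALSE
zebra_finch,hindlimb,III,4,4,TRUE,TRUE,FALSE
zebra_finch,hindlimb,IV,5,5,TRUE,TRUE,FALSE
zebra_finch,hindlimb,V,0,0,FALSE,FALSE,FALSE
ostrich,forelimb,I,0,0,FALSE,FALSE,TRUE
ostrich,forelimb,II,2,2,TRUE,TRUE,TRUE
ostrich,forelimb,III,3,3,TRUE,TRUE,TRUE
ostrich,forelimb,IV,2,2,FALSE,TRUE,TRUE
ostrich,forelimb,V,0,0,FALSE,FALSE,TRUE
ostrich,hindlimb,I,0,0,FALSE,FALSE,TRUE
ostrich,hindlimb,II,0,0,FALSE,FALSE,TRUE
ostrich,hindlimb,III,4,4,TRUE,TRUE,TRUE
ostrich,hindlimb,IV,5,5,FALSE,TRUE,TRUE
ostrich,hindlimb,V,0,0,FALSE,FALSE,TRUE
emu,forelimb,I,0,0,FALSE,FALSE,TRUE
emu,forelimb,II,2,2,TRUE,TRUE,TRUE
emu,forelimb,III,0,0,FALSE,FALSE,TRUE
emu,forelimb,IV,0,0,FALSE,FALSE,TRUE
emu,forelimb,V,0,0,FALSE,FALSE,TRUE
emu,hindlimb,I,0,0,FALSE,FALSE,TRUE
emu,hindlimb,II,3,3,TRUE,TRUE,TRUE
emu,hindlimb,III,4,4,TRUE,TRUE,TRUE
emu,hindlimb,IV,5,5,TRUE,TRUE,TRUE
emu,hindlimb,V,0,0,FALSE,FALSE,TRUE
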