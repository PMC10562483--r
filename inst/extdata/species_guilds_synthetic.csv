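species,guild_id
Salmo trutta,RH_INT
Salmo salar,RH_INT
Thymallus thymallus,RH_INT
Cottus gobio,RH_INT
Barbus barbus,RB_SG
Gobio gobio,RB_SG
Chondrostoma nasus,RB_SG
Barbatula barbatula,RB_SG
Squalius cephalus,RW_SG
Alburnoides bipunctatus,RW_SG
Leuciscus leuciscus,RW_SG
Phoxinus phoxinus,RW_SG
Lampetra planeri,RB_DP
Eudontomyzon mariae,RB_DP
Misgurnus fossilis,RB_DP
Coregonus lavaretus,WC_INT
Hucho hucho,WC_INT
Tinca tinca,LB_MT
Carassius carassius,LB_MT
Abramis brama,LB_MT
Leucaspius delineatus,LW_MT
Scardinius erythrophthalmus,LW_MT
Alburnus alburnus,LW_MT
Rutilus rutilus,LL_MT
Blicca bjoerkna,LL_MT
Esox lucius,LP_MT
Rhodeus amarus,LP_MT
Gymnocephalus cernua,B_MT
Silurus glanis,B_MT
Perca fluviatilis,GEN
Gasterosteus aculeatus,GEN
Anguilla anguilla,GEN
Cyprinus carpio,GEN
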