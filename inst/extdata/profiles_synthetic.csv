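macrohabitat_type,RH_INT,RB_SG,RW_SG,RB_DP,WC_INT,LB_MT,LW_MT,LL_MT,LP_MT,B_MT,GEN
t1,0.55239114299974,0.00718113942166202,0.0270166567127797,0.044470742130153,6.79256140623459e-07,0.0861858090722337,0.0849284126818098,0.00795282634070592,0.00367245319384764,0.178633210786446,0.00756692740448131
t2,0.00288906415841624,0.676913459727195,0.115246749712533,0.0244816131286221,0.136650757909143,0.0162764722078893,0.00181745819413473,0.0149199642933995,8.05567911674157e-05,0.00620254555591236,0.00452135832158777
t3,0.0457598161934384,0.0253046313752813,0.536157351419736,0.172415076017787,0.0024861882953432,0.0277527507567324,1.60648818296297e-05,0.0157519569072221,0.158806428677575,0.0137621853896576,0.00178755008539806
t4,0.0482876043656233,0.000828475587117689,0.00135556594669876,0.636673574937083,0.0512346628536081,0.0649886291497833,0.0158040607997058,0.00400150247090701,0.0537873479810308,0.108236387382545,0.0148021885258973
t5,0.0409739033377663,0.00784060799968807,0.00535983633399298,0.000888472066102464,0.61789552079084,0.000185152699807948,0.227354119161942,0.00159065412179012,8.17789933141989e-06,1.60058868434053e-07,0.0979033955298708
t6,0.00191930150138994,0.000202411734991438,0.175102441321527,0.00269241034668322,0.0114925207709246,0.622326853739528,0.000547634352082759,0.0274393069496551,2.70336206493563e-06,0.000323677622042948,0.15795073829911
t7,0.139064802181962,0.0392338117074834,0.0213894361527891,0.0984212527614442,0.000178059281930465,0.170795983130363,0.435053474082319,0.0279633505829721,0.00131199783606593,0.00775479591632206,0.0588330363663482
t8,0.00572390084908725,0.0316731187203277,6.30301107644244e-05,0.228125545145301,0.0748991960677285,0.0038930342957359,0.0270396803263768,0.313436372557986,0.285838688485911,0.00243451236147152,0.0268729210793098
t9,0.00572245004295002,0.0440385341460489,0.161632384658931,0.000690054232269609,0.00594111657288089,0.0996030707444244,0.00012996458568493,0.0850623159227026,0.466075061539303,0.127044399657892,0.00406064789691181
t10,0.0018319914017167,0.0389069778886906,0.0351014677639663,0.0252410571163247,0.00374732460283806,0.35773514735084,0.0770073099483698,0.058129267223348,0.0363274304433739,0.303915826837132,0.0620561994234005
t11,0.0557035162536283,0.00160710515955165,0.0781474082327219,0.342872248816905,0.00836025543185804,0.00306292649416057,0.00430167850919201,0.000177264146062338,0.00625709911114986,0.00554057706866859,0.493969920776101
t12,0.53452855529214,0.00261672570411192,0.0882768590235106,0.000321858293773728,0.00152541289155732,0.0298470578206521,0.0461519226524053,0.110473447469032,0.137842053087375,0.0408632027513973,0.00755290501404484
t13,0.311702495012384,0.580450358480935,0.0138374588086146,0.000511838571685756,0.0214593989177949,0.0231949537350101,0.00718974860595464,0.0360376343924704,9.49942008233241e-06,0.000956916836331321,0.00464969721873744
t14,0.14781108376712,0.0164567081114982,0.548380616044648,0.0134840560325344,0.0288464217009562,0.130557151523294,0.0124052624247208,0.00134431810919982,0.0125973591754037,0.0170590674905027,0.071057955620121
t15,0.000356561011349917,0.00229219875383435,0.0196952901109893,0.802340522720901,0.00225284543926304,0.000454013568315339,0.000147554860731282,0.0168247503138571,0.000579016677376315,0.000259512390111487,0.154797734153271
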