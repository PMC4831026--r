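taxon,rank,genus,slot1,slot2,slot3,slot4,slot5,slot6,slot7,slot8,slot9
R. norvegicus,species,Rattus,1203.7,1443.7,1451.7,1453.7,2143.1,2695.4,2899.5,2987.5,3003.5
R. rattus,species,Rattus,1203.7,1443.7,1451.7,1453.7,2143.1,2695.4,2899.5,2957.5,3003.5
Apodemus,genus,Apodemus,1203.7,1443.7,1451.7,1453.7,2143.1,2695.4,2910.5,2941.5,3003.5
Micromys,genus,Micromys,1203.7,1443.7,1465.7,1453.7,2143.1,2695.4,2899.5,2943.5,3003.5
Mus,species,Mus,1194.7,1443.7,1451.7,1453.7,2159.1,2695.4,2911.5,2931.5,3013.5
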