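plant_id,piper_species,ecotype,habitat,visitor_taxon,behavior,timestamp
P_reticulatum_1,P. reticulatum,gap,mid,bat,flyby_visit,2019-06-01 18:12:40
P_reticulatum_1,P. reticulatum,gap,mid,bat,remove_fruit,2019-06-01 19:03:12
P_sancti-felicis_1,P. sancti-felicis,gap,early,bat,inspect_fruit,2019-06-01 20:41:05
P_sancti-felicis_1,P. sancti-felicis,gap,early,tanager,remove_fruit,2019-06-02 08:15:33
P_colonense_1,P. colonense,gap,mid,wasp,eat_fruit,2019-06-02 10:02:51
P_generalense_1,P. generalense,forest,mid,bat,remove_fruit,2019-06-02 18:55:20
P_generalense_1,P. generalense,forest,mid,mouse,inspect_fruit,2019-06-02 23:30:00
P_nudifolium_1,P. nudifolium,forest,mid,tapir,whole_plant_consumption,2019-06-03 06:47:10
P_nudifolium_1,P. nudifolium,forest,mid,bat,flyby_visit,2019-06-03 19:22:48
P_paulowniifolium_1,P. paulowniifolium,forest,mid,bat,inspect_fruit,2019-06-03 21:10:02
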