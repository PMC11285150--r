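# SYNTHETIC stand-in for the legend that collapses the 28 vegetation
# classes of a continental land-cover map into 4 broad types. The real
# legend is not published with the analysis; only the totality of the
# mapping (every source code -> one of 4 classes) is contractual.
code,source_class,collapsed
1,closed evergreen lowland forest,forest
2,degraded evergreen lowland forest,forest
3,submontane forest,forest
4,montane forest,forest
5,swamp forest,forest
6,mangrove forest,forest
7,mosaic forest / croplands,mixed_forest_grassland
8,mosaic forest / savanna,mixed_forest_grassland
9,closed deciduous forest,forest
10,deciduous woodland,mixed_forest_grassland
11,deciduous shrubland with sparse trees,mixed_forest_grassland
12,open deciduous shrubland,mixed_forest_grassland
13,closed grassland,grassland
14,open grassland with sparse shrubs,grassland
15,open grassland,grassland
16,sparse grassland,grassland
17,swamp bushland and grassland,grassland
18,croplands (>50%),grassland
19,croplands with open woody vegetation,mixed_forest_grassland
20,irrigated croplands,grassland
21,tree crops,mixed_forest_grassland
22,sandy desert and dunes,bare_ground
23,stony desert,bare_ground
24,bare rock,bare_ground
25,salt hardpans,bare_ground
26,sparse desert vegetation,bare_ground
27,waterbodies margin vegetation,grassland
28,cities,bare_ground
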