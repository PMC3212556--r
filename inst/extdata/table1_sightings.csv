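species,latin_name,common_name,guild,nestbox,control
WEBL,Sialia mexicana,Western Bluebird,I,313,39
CHSP,Spizella passerina,Chipping Sparrow,I,132,100
TRES,Tachycineta bicolor,Tree Swallow,I,4,0
BUOR,Icterus bullockii,Bullock's Oriole,I,0,2
ATFL,Myiarchus cinerascens,Ash-throated Flycatcher,I,1,1
NOFL,Colaptes auratus,Northern Flicker,I,1,1
BLPH,Sayornis nigricans,Black Phoebe,I,1,0
NUWO,Picoides nuttallii,Nuttall's Woodpecker,I,1,0
YRWA,Dendroica coronata,Yellow-rumped Warbler,I,0,1
OCWA,Vermivora celata,Orange-crowned Warbler,I,1,0
WETA,Piranga ludoviciana,Western Tanager,I,1,0
EUST,Sturnus vulgaris,European Starling,O,3,22
BRBL,Euphagus cyanocephalus,Brewer's Blackbird,O,5,8
AMRO,Turdus migratorius,American Robin,O,3,4
LASP,Chondestes grammacus,Lark Sparrow,O,1,2
AMCR,Corvus brachyrhynchos,American Crow,O,0,2
STJA,Cyanocitta stelleri,Steller's Jay,O,2,0
BHCO,Molothrus ater,Brown-headed Cowbird,O,1,0
DEJU,Junco hyemalis,Dark-eyed Junco,O,0,1
AMGO,Spinus tristis,American Goldfinch,G,81,150
HOFI,Carpodacus mexicanus,House Finch,G,67,81
WITU,Meleagris gallopavo,Wild Turkey,G,28,21
LEGO,Carduelis psaltria,Lesser Goldfinch,G,10,17
MODO,Zenaida macroura,Mourning Dove,G,4,5
CALT,Pipilo crissalis,California Towhee,G,0,5
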