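unit,min_mya,max_mya,rank
Holocene,0,0.0117,epoch
Pleistocene,0.0117,2.58,epoch
Gelasian,1.8,2.58,stage
Calabrian,0.774,1.8,stage
Pliocene,2.58,5.333,epoch
Piacenzian,2.58,3.6,stage
Zanclean,3.6,5.333,stage
Miocene,5.333,23.03,epoch
Messinian,5.333,7.246,stage
Tortonian,7.246,11.63,stage
Serravallian,11.63,13.82,stage
Langhian,13.82,15.97,stage
Burdigalian,15.97,20.44,stage
Aquitanian,20.44,23.03,stage
Oligocene,23.03,33.9,epoch
Chattian,23.03,27.82,stage
Rupelian,27.82,33.9,stage
Eocene,33.9,56,epoch
Priabonian,33.9,37.71,stage
Bartonian,37.71,41.2,stage
Lutetian,41.2,47.8,stage
Ypresian,47.8,56,stage
Paleocene,56,66,epoch
Thanetian,56,59.2,stage
Selandian,59.2,61.6,stage
Danian,61.6,66,stage
Quaternary,0,2.58,period
Neogene,2.58,23.03,period
Paleogene,23.03,66,period
Cretaceous,66,145,period
Late Cretaceous,66,100.5,epoch
Upper Cretaceous,66,100.5,epoch
Maastrichtian,66,72.1,stage
Campanian,72.1,83.6,stage
Santonian,83.6,86.3,stage
Coniacian,86.3,89.8,stage
Turonian,89.8,93.9,stage
Cenomanian,93.9,100.5,stage
Early Cretaceous,100.5,145,epoch
Lower Cretaceous,100.5,145,epoch
Albian,100.5,113,stage
Aptian,113,125,stage
Barremian,125,129.4,stage
Hauterivian,129.4,132.6,stage
Valanginian,132.6,139.8,stage
Berriasian,139.8,145,stage
Jurassic,145,201.3,period
Late Jurassic,145,163.5,epoch
Upper Jurassic,145,163.5,epoch
Tithonian,145,152.1,stage
Kimmeridgian,152.1,157.3,stage
Oxfordian,157.3,163.5,stage
Middle Jurassic,163.5,174.1,epoch
Callovian,163.5,166.1,stage
Bathonian,166.1,168.3,stage
Bajocian,168.3,170.3,stage
Aalenian,170.3,174.1,stage
Early Jurassic,174.1,201.3,epoch
Lower Jurassic,174.1,201.3,epoch
Toarcian,174.1,182.7,stage
Pliensbachian,182.7,190.8,stage
Sinemurian,190.8,199.3,stage
Hettangian,199.3,201.3,stage
Triassic,201.3,251.902,period
Late Triassic,201.3,237,epoch
Rhaetian,201.3,208.5,stage
Norian,208.5,227,stage
Carnian,227,237,stage
Middle Triassic,237,247.2,epoch
Ladinian,237,242,stage
Anisian,242,247.2,stage
Early Triassic,247.2,251.902,epoch
Olenekian,247.2,251.2,stage
Induan,251.2,251.902,stage
Cenozoic,0,66,era
Mesozoic,66,251.902,era
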