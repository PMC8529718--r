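record_id,taxon,family,genus,region,geologic_age,source,suspect
f001,Orectolobus sp.,Orectolobidae,Orectolobus,Europe,Cenomanian,synthetic fixture,FALSE
f002,Orectolobus sp.,Orectolobidae,Orectolobus,North America,Campanian-Maastrichtian,synthetic fixture,FALSE
f003,Brachaelurus sp.,Brachaeluridae,Brachaelurus,North America,Ypresian,synthetic fixture,FALSE
f004,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,North America,Maastrichtian,synthetic fixture,FALSE
f005,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,Africa,Eocene,synthetic fixture,FALSE
f006,Nebrius sp.,Ginglymostomatidae,Nebrius,Europe,Lutetian,synthetic fixture,FALSE
f007,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,Africa,Burdigalian,synthetic fixture,FALSE
f008,Rhincodon sp.,Rhincodontidae,Rhincodon,Africa,Rupelian,synthetic fixture,FALSE
f009,Rhincodon sp.,Rhincodontidae,Rhincodon,Asia,Chattian,synthetic fixture,FALSE
f010,Stegostoma sp.,Stegostomatidae,Stegostoma,Europe,Thanetian,synthetic fixture,FALSE
f011,Pseudoginglymostoma sp.,Ginglymostomatidae,Pseudoginglymostoma,Africa,Ypresian,synthetic fixture,FALSE
f012,Chiloscyllium sp.,Hemiscylliidae,Chiloscyllium,North America,Santonian,synthetic fixture,FALSE
f013,Hemiscyllium sp.,Hemiscylliidae,Hemiscyllium,Europe,Campanian,synthetic fixture,FALSE
f014,Orectolobus sp.,Orectolobidae,Orectolobus,Australia,70-75 MYA,synthetic fixture,FALSE
f015,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,Europe,Danian,synthetic fixture,FALSE
f016,Orectolobus sp.,Orectolobidae,Orectolobus,Europe,Turonian,synthetic fixture,TRUE
f017,Orectolobiformes indet.,,,Asia,Campanian,synthetic fixture,FALSE
f018,Pararhincodon sp.,,Pararhincodon,Europe,Cenomanian,synthetic fixture,FALSE
f019,Parascyllium sp.,Parascylliidae,Parascyllium,Australia,Zanclean,synthetic fixture,FALSE
f020,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,Africa,Mesozoicish,synthetic fixture,FALSE
f021,Ginglymostoma sp.,Ginglymostomatidae,Ginglymostoma,Europe,Albian,synthetic fixture,FALSE
f022,Chiloscyllium sp.,Hemiscylliidae,Chiloscyllium,North America,Priabonian,synthetic fixture,FALSE
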