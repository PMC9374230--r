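origin,group,indicator,weight
internal,strengths,Size of area,100
internal,strengths,Food availability,100
internal,strengths,Vegetation,100
internal,strengths,Medicinal importance,80
internal,strengths,Socioeconomic importance,70
internal,strengths,Connectivity,70
internal,strengths,Climate,80
internal,strengths,Topography,70
internal,strengths,Available natural resources,70
internal,strengths,Biodiversity,80
internal,strengths,Ecological role of species,30
internal,weaknesses,Risk of native species,70
internal,weaknesses,Risk of diseases,60
internal,weaknesses,Risk of flood,90
internal,weaknesses,Soil erosion,60
internal,weaknesses,Agricultural practices,90
internal,weaknesses,Competition with other native species,60
external,opportunities,Habitat protection by irrigation department,80
external,opportunities,Management plan for the area,70
external,opportunities,Forest Department,80
external,opportunities,Existing conservation program,50
external,opportunities,Conservation unit,60
external,opportunities,Existing tourism involvement,60
external,opportunities,Public involvement,50
external,threats,Competition by exotic plants,60
external,threats,Grazing,80
external,threats,Anthropogenic activities within the area,60
external,threats,Risk of human infrastructure within area,70
external,threats,Fish farming,70
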