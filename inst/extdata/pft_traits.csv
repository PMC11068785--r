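# Repository-supplied vegetation trait defaults per plant functional type.
# Canopy height h_c (m) and root-depth quantiles D50/D95 (cm) from published
# ecosystem syntheses of rooting profiles; approximate class values, editable.
pft,h_c,d50,d95
grassland,0.6,16,80
cropland,1.0,20,95
shrubland,2.0,25,130
savanna,5.0,22,140
deciduous_broadleaf_forest,20.0,20,150
evergreen_needleleaf_forest,17.0,18,140
evergreen_broadleaf_forest,30.0,25,180
wetland,0.8,12,60
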