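# Repository-supplied soil hydraulic defaults per USDA texture class.
# Clapp-Hornberger/Cosby-style values (theta_s, b, k_sat) with field capacity
# (-33 kPa) and wilting point (-1500 kPa); approximate class means, editable.
# Columns: theta_s, theta_fc, theta_wp (m3 m-3); b (-); k_sat (mm d-1).
texture,theta_s,theta_fc,theta_wp,b,k_sat
sand,0.395,0.174,0.059,4.05,1056
loamy_sand,0.410,0.179,0.075,4.38,564
sandy_loam,0.435,0.249,0.114,4.90,176
loam,0.451,0.270,0.117,5.39,135
silt_loam,0.485,0.330,0.133,5.30,72
sandy_clay_loam,0.420,0.299,0.175,7.12,43
clay_loam,0.476,0.339,0.197,8.52,25
silty_clay,0.492,0.387,0.250,10.40,17
clay,0.482,0.396,0.272,11.40,13
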