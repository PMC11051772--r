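variable,unit,description
temperature,degC,sea water temperature at sampling depth
salinity,PSU,practical salinity
density,kg m-3,potential density anomaly
kd_par,m-1,attenuation coefficient of photosynthetically available radiation
cml_depth,m,depth of the chlorophyll maximum layer
mld,m,mixed layer depth
nitracline_depth,m,depth where nitrate starts increasing sharply
euphotic_depth,m,depth of 1 percent surface irradiance
par_8d,mol photons m-2 d-1,photosynthetically available radiation (8-day median)
par_30d,mol photons m-2 d-1,photosynthetically available radiation (30-day median)
sunshine_duration,h d-1,climatological sunshine duration
chl_a,mg m-3,total chlorophyll a
oxygen,umol kg-1,dissolved oxygen
no3_no2,umol L-1,dissolved nitrate plus nitrite
no2,umol L-1,dissolved nitrite
po4,umol L-1,dissolved phosphate
sio4,umol L-1,dissolved silicate
ph,total scale,sea water pH
total_alkalinity,umol kg-1,total alkalinity
total_carbon,umol kg-1,dissolved inorganic carbon
fluorescence,RFU,in situ chlorophyll fluorescence
poc,umol kg-1,particulate organic carbon
pic,umol kg-1,particulate inorganic carbon
cdom,ppb,colored dissolved organic matter (synthetic registry entry)
pco2,uatm,partial pressure of CO2
npp,mg C m-2 d-1,net primary production (synthetic registry entry)
prochlorococcus,cells mL-1,Prochlorococcus abundance
synechococcus,cells mL-1,Synechococcus abundance
het_bacteria,cells mL-1,heterotrophic bacteria abundance
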