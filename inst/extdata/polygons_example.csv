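id,area_ha,soil_group,sand,silt,clay,bulk_density,ph,initial_socc,lon,lat
EX01,3200,aeolian sandy soil,0.7836,0.0972,0.1192,1.46,8.1,5.51,122.4,45.1
EX02,5400,black soil,0.3869,0.4308,0.1823,1.16,7.2,23.2,125.3,43.9
EX03,6100,chernozem,0.3449,0.4064,0.2487,1.3,7.8,19.082,124.1,44.6
EX04,4800,dark brown forest soil,0.4709529,0.3189681,0.21007899,1.07,5.85,23.954,128.9,43.2
EX05,5900,meadow soil,0.33386661,0.46545345,0.20067993,1.3,5.7,19.459,126.2,44.9
EX06,1500,planosol,0.20287971,0.57384262,0.22327767,1.38,5.05,22.098,129.8,43.5
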