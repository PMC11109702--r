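label,kind,lon,lat
Karonga,malawi_town,33.933,-9.933
Chilumba,malawi_town,34.166,-10.427
Chitipa,malawi_town,33.270,-9.702
Rumphi,malawi_town,33.859,-11.018
Mzuzu,malawi_town,34.020,-11.465
Nkhata Bay,malawi_town,34.297,-11.606
Kasungu,malawi_town,33.483,-13.033
Lilongwe,malawi_town,33.783,-13.983
Zomba,malawi_town,35.319,-15.386
Blantyre,malawi_town,35.005,-15.786
Tanzania,foreign_country,33.947,-9.568
Zambia,foreign_country,33.216,-9.817
Mozambique,foreign_country,35.418,-14.421
Zimbabwe,foreign_country,30.430,-15.616
South Africa,foreign_country,29.467,-22.218
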