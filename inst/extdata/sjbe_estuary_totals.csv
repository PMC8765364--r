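quantity,value
ag_stock_mg,830.7
soil_recent_mg,16340.0
soil_historic_mg,5422.5
ag_accum_mg_y,52.73
soil_recent_accum_mg_y,405.3
soil_historic_accum_mg_y,174.0
mangrove_area_ha,2313
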