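areal_type,affinity
North Temperate,temperate
East Asia and North America,temperate
Old World Temperate,temperate
Temperate Asia,temperate
"Mediterranean, West to Central Asia",temperate
Central Asia,temperate
East Asia,temperate
North Asia,temperate
Old World Temperate regions,temperate
Tropical Asia and Tropical America,tropical
Old World Tropics,tropical
Old World Tropic regions,tropical
Tropical Asia to Tropical Australia,tropical
Tropical Asia to Tropical Africa,tropical
Tropical Asia,tropical
Pantropic,tropical
Cosmopolitan,cosmopolitan
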