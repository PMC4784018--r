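country,source_area_1e3km2,receptor_area_1e3km2,min_dist_km,source_limiting,receptor_limiting,distance_limiting
Turkey,225.564,99.797,0,FALSE,FALSE,FALSE
Mexico,192.261,330.998,0,FALSE,FALSE,FALSE
Madagascar,191.450,199.523,0,FALSE,FALSE,FALSE
Thailand,81.181,54.266,0,FALSE,FALSE,FALSE
United States,56.858,124.758,0,FALSE,FALSE,FALSE
Nigeria,50.606,372.483,0,FALSE,FALSE,FALSE
Myanmar,35.007,41.385,12,FALSE,FALSE,FALSE
Cameroon,33.907,133.513,0,FALSE,FALSE,FALSE
Vietnam,33.394,84.512,0,FALSE,FALSE,FALSE
Iran,29.814,56.357,212,FALSE,FALSE,FALSE
Indonesia,26.200,193.764,59,FALSE,FALSE,FALSE
Australia,25.241,77.190,895,FALSE,FALSE,TRUE
Brazil,17.338,110.477,2067,FALSE,FALSE,TRUE
Cambodia,31.448,13.063,0,FALSE,TRUE,FALSE
Kazakhstan,47.915,6.220,0,FALSE,TRUE,FALSE
Mozambique,19.228,3.757,125,FALSE,TRUE,FALSE
Uzbekistan,71.783,1.390,48,FALSE,TRUE,FALSE
Azerbaijan,50.529,0.807,0,FALSE,TRUE,FALSE
Russian Federation,22.149,0.313,111,FALSE,TRUE,FALSE
South Africa,12.459,272.566,0,TRUE,FALSE,FALSE
Malaysia,7.924,59.212,3,TRUE,FALSE,FALSE
Colombia,6.007,151.639,22,TRUE,FALSE,FALSE
Yemen,3.722,174.707,388,TRUE,FALSE,FALSE
Eritrea,2.848,76.981,232,TRUE,FALSE,FALSE
Philippines,0.236,168.094,38,TRUE,FALSE,FALSE
Cuba,11.976,1.735,0,TRUE,TRUE,FALSE
Laos,11.564,0.620,0,TRUE,TRUE,FALSE
Dominican Republic,8.754,0.211,73,TRUE,TRUE,FALSE
Puerto Rico,8.641,0.094,0,TRUE,TRUE,FALSE
Morocco,6.328,2.043,34,TRUE,TRUE,FALSE
Panama,6.098,8.189,2,TRUE,TRUE,FALSE
Tajikistan,3.877,4.157,89,TRUE,TRUE,FALSE
Haiti,3.431,0.293,3,TRUE,TRUE,FALSE
Guatemala,2.633,2.067,70,TRUE,TRUE,FALSE
El Salvador,0.642,0.063,33,TRUE,TRUE,FALSE
Kyrgyzstan,0.394,0.128,158,TRUE,TRUE,FALSE
Georgia,13.127,3.720,0,TRUE,TRUE,FALSE
Chile,0.045,61.907,628,TRUE,FALSE,TRUE
Ecuador,7.813,8.460,927,TRUE,TRUE,TRUE
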