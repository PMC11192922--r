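id,name,year,fitting_coefficient,constant_term,industrial_structure,fdi,urbanization,residual,standard_error
Shanghai,Shanghai,2013,0.370,0.785,0.242,-0.245,-0.433,-0.265,0.156
Yunnan,Yunnan,2013,0.327,0.773,0.281,-0.167,-0.448,0.090,0.177
Neimenggu,Neimenggu,2013,0.337,0.758,0.219,-0.277,-0.372,0.084,0.183
Beijing,Beijing,2013,0.349,0.767,0.227,-0.268,-0.393,0.040,0.070
Jilin,Jilin,2013,0.364,0.773,0.214,-0.308,-0.380,0.169,0.185
Sichuan,Sichuan,2013,0.326,0.765,0.261,-0.192,-0.426,0.128,0.186
Tianjin,Tianjin,2013,0.352,0.769,0.229,-0.266,-0.397,-0.256,0.149
Ningxia,Ningxia,2013,0.328,0.759,0.239,-0.229,-0.399,-0.114,0.187
Anhui,Anhui,2013,0.361,0.780,0.246,-0.236,-0.430,-0.166,0.187
Shandong,Shandong,2013,0.358,0.774,0.235,-0.256,-0.411,-0.300,0.188
Shanxi_1,Shanxi,2013,0.343,0.766,0.236,-0.246,-0.403,-0.044,0.186
Guangdong,Guangdong,2013,0.360,0.790,0.271,-0.195,-0.461,0.253,0.158
Guangxi,Guangxi,2013,0.349,0.784,0.277,-0.183,-0.457,0.245,0.184
Xinjiang,Xinjiang,2013,0.253,0.721,0.218,-0.197,-0.345,-0.181,0.177
Jiangsu,Jiangsu,2013,0.364,0.781,0.241,-0.246,-0.426,-0.081,0.120
Jiangxi,Jiangxi,2013,0.362,0.785,0.257,-0.216,-0.446,0.112,0.186
Henan,Henan,2013,0.351,0.773,0.245,-0.234,-0.420,-0.239,0.186
Zhejiang,Zhejiang,2013,0.370,0.787,0.248,-0.234,-0.441,0.183,0.186
Hainan,Hainan,2013,0.355,0.792,0.288,-0.171,-0.472,0.160,0.155
Hubei,Hubei,2013,0.351,0.776,0.253,-0.219,-0.432,0.027,0.188
Hunan,Hunan,2013,0.353,0.781,0.262,-0.205,-0.445,-0.004,0.188
Gansu,Gansu,2013,0.312,0.751,0.238,-0.219,-0.391,-0.147,0.180
Fujian,Fujian,2013,0.368,0.790,0.258,-0.217,-0.453,0.320,0.183
Guizhou,Guizhou,2013,0.341,0.777,0.270,-0.189,-0.445,-0.142,0.175
Liaoning,Liaoning,2013,0.360,0.772,0.221,-0.288,-0.390,0.176,0.181
Chongqing,Chongqing,2013,0.341,0.773,0.260,-0.204,-0.433,0.093,0.186
Shanxi_2,Shanxi,2013,0.338,0.766,0.244,-0.227,-0.412,0.096,0.186
Qinghai,Qinghai,2013,0.299,0.748,0.245,-0.197,-0.395,-0.151,0.185
Heilongjiang,Heilongjiang,2013,0.361,0.770,0.205,-0.330,-0.361,0.229,0.178
Hebei,Hebei,2013,0.349,0.767,0.229,-0.264,-0.396,-0.185,0.187
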