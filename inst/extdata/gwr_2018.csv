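id,name,year,fitting_coefficient,constant_term,industrial_structure,fdi,urbanization,residual,standard_error
Shanghai,Shanghai,2018,0.359,0.760,0.438,-0.038,-0.694,-0.213,0.166
Yunnan,Yunnan,2018,0.328,0.744,0.523,0.094,-0.668,0.064,0.187
Neimenggu,Neimenggu,2018,0.331,0.706,0.467,-0.181,-0.587,0.117,0.197
Beijing,Beijing,2018,0.344,0.723,0.467,-0.132,-0.628,0.020,0.060
Jilin,Jilin,2018,0.400,0.756,0.521,-0.288,-0.652,0.195,0.195
Sichuan,Sichuan,2018,0.310,0.723,0.463,0.064,-0.645,0.115,0.202
Tianjin,Tianjin,2018,0.347,0.727,0.466,-0.123,-0.637,-0.167,0.150
Ningxia,Ningxia,2018,0.304,0.703,0.436,-0.018,-0.608,-0.232,0.202
Anhui,Anhui,2018,0.350,0.750,0.445,-0.018,-0.685,-0.204,0.204
Shandong,Shandong,2018,0.349,0.737,0.457,-0.082,-0.658,-0.356,0.206
Shanxi_1,Shanxi,2018,0.329,0.718,0.450,-0.059,-0.632,-0.035,0.205
Guangdong,Guangdong,2018,0.363,0.781,0.472,0.062,-0.722,0.141,0.073
Guangxi,Guangxi,2018,0.354,0.769,0.497,0.075,-0.705,0.194,0.196
Xinjiang,Xinjiang,2018,0.139,0.598,0.322,0.096,-0.407,-0.156,0.169
Jiangsu,Jiangsu,2018,0.354,0.750,0.446,-0.045,-0.681,-0.241,0.178
Jiangxi,Jiangxi,2018,0.355,0.766,0.446,0.029,-0.707,0.129,0.203
Henan,Henan,2018,0.339,0.735,0.448,-0.019,-0.663,-0.275,0.202
Zhejiang,Zhejiang,2018,0.359,0.766,0.434,-0.009,-0.704,0.231,0.199
Hainan,Hainan,2018,0.373,0.788,0.533,0.081,-0.717,0.178,0.139
Hubei,Hubei,2018,0.341,0.745,0.450,0.018,-0.679,0.090,0.206
Hunan,Hunan,2018,0.348,0.759,0.461,0.047,-0.698,0.017,0.206
Gansu,Gansu,2018,0.274,0.683,0.419,0.005,-0.572,-0.163,0.182
Fujian,Fujian,2018,0.361,0.777,0.438,0.028,-0.718,0.366,0.192
Guizhou,Guizhou,2018,0.339,0.752,0.483,0.069,-0.686,-0.080,0.193
Liaoning,Liaoning,2018,0.373,0.741,0.492,-0.205,-0.645,0.187,0.201
Chongqing,Chongqing,2018,0.331,0.740,0.460,0.046,-0.671,0.227,0.197
Shanxi_2,Shanxi,2018,0.321,0.719,0.445,-0.007,-0.637,0.147,0.204
Qinghai,Qinghai,2018,0.250,0.676,0.416,0.059,-0.561,-0.133,0.199
Heilongjiang,Heilongjiang,2018,0.427,0.772,0.555,-0.395,-0.653,0.202,0.186
Hebei,Hebei,2018,0.343,0.723,0.464,-0.118,-0.631,-0.142,0.204
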