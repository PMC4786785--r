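id,formula,name
5a,C8H7NO2,trans-beta-nitrostyrene
6a,C10H11NO3,4-nitro-3-phenylbutanal
6b,C10H10ClNO3,3-(4-chlorophenyl)-4-nitrobutanal
6c,C10H10FNO3,3-(4-fluorophenyl)-4-nitrobutanal
6d,C10H11NO4,3-(4-hydroxyphenyl)-4-nitrobutanal
6e,C11H13NO5,3-(3-hydroxy-4-methoxyphenyl)-4-nitrobutanal
6f,C16H21NO5,3-(3-(cyclopentyloxy)-4-methoxyphenyl)-4-nitrobutanal
6g,C8H15NO3,5-methyl-3-(nitromethyl)hexanal
7,C12H15NO3,2-ethyl-4-nitro-3-phenylbutanal
10,C8H9NO3,2-nitro-1-phenylethanol
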