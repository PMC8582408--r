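id,rmin,rmax,gmin,gmax,bmin,bmax
cl1,0,15,0,15,0,15
cl2,21,39,13,31,6,24
cl3,41,59,27,45,16,34
cl4,61,79,41,59,26,44
cl5,81,99,56,74,36,54
cl6,101,119,70,88,46,64
cl7,121,139,85,103,56,74
cl8,141,159,99,117,66,84
cl9,161,179,113,131,76,94
cl10,181,199,128,146,86,104
cl11,201,219,142,160,96,114
cl12,51,69,66,84,111,129
cl13,81,99,96,114,141,159
cl14,111,129,126,144,171,189
cl15,141,159,156,174,201,219
cl16,136,164,30,60,30,60
cl17,166,194,30,60,30,60
cl18,196,224,30,60,30,60
cl19,226,254,30,60,30,60
cl20,170,195,115,145,140,170
cl21,196,224,130,160,140,170
cl22,225,245,225,245,225,245
cl23,246,255,246,255,246,255
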