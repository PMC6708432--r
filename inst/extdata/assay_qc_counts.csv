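assay_id,validated,val_total,fail,miscall_high,miscall_low,het_as_hom,low_depth,test_genotyped,test_total,geno_lt3,conflict,miss,excluded
106_236865_4418,39,44,2,2,1,2,1,32,40,9,3,5,0
1097_90776_5934,12,43,16,6,9,7,1,34,40,7,4,2,1
12014_11876_11681,24,44,18,0,2,2,0,21,40,9,1,18,0
1271_66264_14951,34,42,4,2,2,0,1,33,40,2,4,3,0
13195_13998_17239,34,38,4,0,0,0,0,34,40,9,3,3,0
13448_11843_18246,35,43,7,1,0,1,0,29,40,8,3,8,0
13906_6774_20306,40,44,3,0,1,1,0,39,40,13,1,0,0
1451_61933_23204,17,44,27,0,0,0,0,22,40,7,0,18,1
146_152030_23838,33,43,4,6,0,3,2,33,40,6,0,7,1
1585_55938_28568,35,41,5,1,0,1,0,30,40,16,1,9,0
169_46093_32582,33,42,3,3,3,1,1,30,40,10,3,7,0
169_115167_32520,34,43,8,0,1,1,0,30,40,8,1,9,0
169_157168_32535,35,40,4,0,1,1,1,34,40,15,1,5,0
1738_69256_34014,34,41,3,1,3,3,0,36,40,6,0,4,0
17836_10023_35444,38,42,4,0,0,2,0,32,40,9,4,4,0
18308_3413_37089,40,44,2,0,2,1,0,31,40,8,6,3,0
250_760_56581,40,42,2,0,0,0,0,37,40,10,0,3,0
2564_11816_57667,33,41,6,1,1,1,1,24,40,4,7,9,0
270_3398_60937,35,43,6,0,2,2,2,23,40,11,0,17,0
37767_810_80534,27,43,8,7,1,7,2,28,40,16,2,10,0
4501_1340_91074,34,44,5,1,4,5,1,33,40,17,1,6,0
4808_30565_94636,30,42,12,0,0,0,0,31,40,10,0,9,0
5231_23669_99330,36,42,4,1,1,0,0,33,40,11,6,1,0
528_23389_99792,36,42,4,1,1,2,1,32,40,12,1,7,0
62_334436_109976,38,43,4,1,0,1,0,25,40,12,9,6,0
636_114293_110548,27,43,12,3,1,4,1,28,40,9,0,12,0
64_189228_111723,31,42,10,1,0,1,0,31,40,12,2,7,0
70_287186_117070,24,41,4,6,7,7,2,29,40,10,5,6,1
729_2947_118563,27,40,6,6,1,6,1,19,40,9,1,20,0
770_72175_121997,37,41,3,1,0,1,0,34,40,13,0,6,0
908_61119_132233,34,43,9,0,0,0,0,35,40,6,1,4,0
952_3897_135282,35,43,3,4,1,3,0,36,40,6,4,0,0
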