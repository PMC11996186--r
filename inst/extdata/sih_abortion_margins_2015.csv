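region,age_band,count
AC,10-19,249
AC,20-29,510
AC,30-39,322
AC,40-49,66
AL,10-19,686
AL,20-29,1358
AL,30-39,781
AL,40-49,167
AM,10-19,616
AM,20-29,1242
AM,30-39,747
AM,40-49,173
AP,10-19,252
AP,20-29,677
AP,30-39,434
AP,40-49,78
BA,10-19,2264
BA,20-29,5528
BA,30-39,4100
BA,40-49,772
CE,10-19,1332
CE,20-29,3460
CE,30-39,2405
CE,40-49,618
DF,10-19,264
DF,20-29,726
DF,30-39,661
DF,40-49,147
ES,10-19,374
ES,20-29,991
ES,30-39,730
ES,40-49,179
GO,10-19,538
GO,20-29,1384
GO,30-39,927
GO,40-49,175
MA,10-19,1123
MA,20-29,2498
MA,30-39,1216
MA,40-49,186
MG,10-19,2036
MG,20-29,5699
MG,30-39,4453
MG,40-49,1065
MS,10-19,282
MS,20-29,620
MS,30-39,417
MS,40-49,78
MT,10-19,324
MT,20-29,774
MT,30-39,450
MT,40-49,91
PA,10-19,1467
PA,20-29,3028
PA,30-39,1396
PA,40-49,264
PB,10-19,639
PB,20-29,1520
PB,30-39,1156
PB,40-49,250
PE,10-19,1612
PE,20-29,3751
PE,30-39,2441
PE,40-49,519
PI,10-19,467
PI,20-29,1001
PI,30-39,618
PI,40-49,127
PR,10-19,759
PR,20-29,1887
PR,30-39,1384
PR,40-49,374
RJ,10-19,2049
RJ,20-29,5160
RJ,30-39,3452
RJ,40-49,699
RN,10-19,549
RN,20-29,1269
RN,30-39,898
RN,40-49,218
RO,10-19,268
RO,20-29,737
RO,30-39,424
RO,40-49,88
RR,10-19,173
RR,20-29,448
RR,30-39,282
RR,40-49,50
RS,10-19,663
RS,20-29,1783
RS,30-39,1575
RS,40-49,445
SC,10-19,454
SC,20-29,1286
SC,30-39,1034
SC,40-49,231
SE,10-19,522
SE,20-29,1243
SE,30-39,857
SE,40-49,169
SP,10-19,3602
SP,20-29,10122
SP,30-39,7699
SP,40-49,2011
TO,10-19,348
TO,20-29,786
TO,30-39,460
TO,40-49,95
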