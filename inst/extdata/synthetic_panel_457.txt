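HLA-B
BTG2
MCL1
H3F3A
MYC
KMT2C
KYAT3
ARID4B
CD22
TGFB1
SGK1
RSPO2
TP53
PIK3CA
ARID1A
CIC
KMT2D
NOTCH4
PBRM1
PTEN
DNMT3A
HLA-C
HLA-A
HLA-DRB1
SPPL3
C8orf34
HLA-DQA1
HLA-E
LTBP1
SYN001
SYN002
SYN003
SYN004
SYN005
SYN006
SYN007
SYN008
SYN009
SYN010
SYN011
SYN012
SYN013
SYN014
SYN015
SYN016
SYN017
SYN018
SYN019
SYN020
SYN021
SYN022
SYN023
SYN024
SYN025
SYN026
SYN027
SYN028
SYN029
SYN030
SYN031
SYN032
SYN033
SYN034
SYN035
SYN036
SYN037
SYN038
SYN039
SYN040
SYN041
SYN042
SYN043
SYN044
SYN045
SYN046
SYN047
SYN048
SYN049
SYN050
SYN051
SYN052
SYN053
SYN054
SYN055
SYN056
SYN057
SYN058
SYN059
SYN060
SYN061
SYN062
SYN063
SYN064
SYN065
SYN066
SYN067
SYN068
SYN069
SYN070
SYN071
SYN072
SYN073
SYN074
SYN075
SYN076
SYN077
SYN078
SYN079
SYN080
SYN081
SYN082
SYN083
SYN084
SYN085
SYN086
SYN087
SYN088
SYN089
SYN090
SYN091
SYN092
SYN093
SYN094
SYN095
SYN096
SYN097
SYN098
SYN099
SYN100
SYN101
SYN102
SYN103
SYN104
SYN105
SYN106
SYN107
SYN108
SYN109
SYN110
SYN111
SYN112
SYN113
SYN114
SYN115
SYN116
SYN117
SYN118
SYN119
SYN120
SYN121
SYN122
SYN123
SYN124
SYN125
SYN126
SYN127
SYN128
SYN129
SYN130
SYN131
SYN132
SYN133
SYN134
SYN135
SYN136
SYN137
SYN138
SYN139
SYN140
SYN141
SYN142
SYN143
SYN144
SYN145
SYN146
SYN147
SYN148
SYN149
SYN150
SYN151
SYN152
SYN153
SYN154
SYN155
SYN156
SYN157
SYN158
SYN159
SYN160
SYN161
SYN162
SYN163
SYN164
SYN165
SYN166
SYN167
SYN168
SYN169
SYN170
SYN171
SYN172
SYN173
SYN174
SYN175
SYN176
SYN177
SYN178
SYN179
SYN180
SYN181
SYN182
SYN183
SYN184
SYN185
SYN186
SYN187
SYN188
SYN189
SYN190
SYN191
SYN192
SYN193
SYN194
SYN195
SYN196
SYN197
SYN198
SYN199
SYN200
SYN201
SYN202
SYN203
SYN204
SYN205
SYN206
SYN207
SYN208
SYN209
SYN210
SYN211
SYN212
SYN213
SYN214
SYN215
SYN216
SYN217
SYN218
SYN219
SYN220
SYN221
SYN222
SYN223
SYN224
SYN225
SYN226
SYN227
SYN228
SYN229
SYN230
SYN231
SYN232
SYN233
SYN234
SYN235
SYN236
SYN237
SYN238
SYN239
SYN240
SYN241
SYN242
SYN243
SYN244
SYN245
SYN246
SYN247
SYN248
SYN249
SYN250
SYN251
SYN252
SYN253
SYN254
SYN255
SYN256
SYN257
SYN258
SYN259
SYN260
SYN261
SYN262
SYN263
SYN264
SYN265
SYN266
SYN267
SYN268
SYN269
SYN270
SYN271
SYN272
SYN273
SYN274
SYN275
SYN276
SYN277
SYN278
SYN279
SYN280
SYN281
SYN282
SYN283
SYN284
SYN285
SYN286
SYN287
SYN288
SYN289
SYN290
SYN291
SYN292
SYN293
SYN294
SYN295
SYN296
SYN297
SYN298
SYN299
SYN300
SYN301
SYN302
SYN303
SYN304
SYN305
SYN306
SYN307
SYN308
SYN309
SYN310
SYN311
SYN312
SYN313
SYN314
SYN315
SYN316
SYN317
SYN318
SYN319
SYN320
SYN321
SYN322
SYN323
SYN324
SYN325
SYN326
SYN327
SYN328
SYN329
SYN330
SYN331
SYN332
SYN333
SYN334
SYN335
SYN336
SYN337
SYN338
SYN339
SYN340
SYN341
SYN342
SYN343
SYN344
SYN345
SYN346
SYN347
SYN348
SYN349
SYN350
SYN351
SYN352
SYN353
SYN354
SYN355
SYN356
SYN357
SYN358
SYN359
SYN360
SYN361
SYN362
SYN363
SYN364
SYN365
SYN366
SYN367
SYN368
SYN369
SYN370
SYN371
SYN372
SYN373
SYN374
SYN375
SYN376
SYN377
SYN378
SYN379
SYN380
SYN381
SYN382
SYN383
SYN384
SYN385
SYN386
SYN387
SYN388
SYN389
SYN390
SYN391
SYN392
SYN393
SYN394
SYN395
SYN396
SYN397
SYN398
SYN399
SYN400
SYN401
SYN402
SYN403
SYN404
SYN405
SYN406
SYN407
SYN408
SYN409
SYN410
SYN411
SYN412
SYN413
SYN414
SYN415
SYN416
SYN417
SYN418
SYN419
SYN420
SYN421
SYN422
SYN423
SYN424
SYN425
SYN426
SYN427
SYN428
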