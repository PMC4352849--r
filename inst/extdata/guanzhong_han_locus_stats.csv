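locus,n,pd,pic,pe,tpi,ho,he,hwe_p
D6S474,275,0.8576,0.6476,0.4199,1.6369,0.6945,0.7000,0.8062
D12ATA63,275,0.8858,0.6825,0.4034,1.5805,0.6836,0.7278,0.0898
D22S1045,275,0.8979,0.7243,0.5790,2.3707,0.7891,0.7644,0.3622
D10S1248,275,0.8906,0.7057,0.5144,2.0221,0.7527,0.7468,0.8618
D1S1677,275,0.7898,0.5527,0.2822,1.2277,0.5927,0.6136,0.4535
D11S4463,275,0.9034,0.7192,0.4540,1.7628,0.7164,0.7582,0.0938
D1S1627,275,0.7700,0.5325,0.2865,1.2387,0.5964,0.5940,0.9664
D3S4529,275,0.8775,0.6787,0.4255,1.6566,0.6982,0.7219,0.3543
D2S441,275,0.9072,0.7299,0.5082,1.9928,0.7491,0.7653,0.4888
D6S1017,275,0.8828,0.6870,0.4599,1.7857,0.7200,0.7329,0.5919
D4S2408,275,0.8863,0.6994,0.4717,1.8333,0.7273,0.7453,0.4591
D19S433,275,0.9437,0.7916,0.5856,2.4123,0.7927,0.8147,0.3147
D17S1301,275,0.8753,0.6672,0.4540,1.7628,0.7164,0.7063,0.7501
D1GATA113,275,0.8091,0.5674,0.2738,1.2061,0.5855,0.6285,0.1289
D18S853,275,0.8566,0.6713,0.5462,2.1825,0.7709,0.7180,0.0567
D20S482,275,0.8975,0.7107,0.5144,2.0221,0.7527,0.7475,0.8824
D14S1434,275,0.8825,0.6822,0.4658,1.8092,0.7236,0.7276,0.8448
D9S1122,275,0.8852,0.6915,0.4599,1.7857,0.7200,0.7352,0.5327
D2S1776,275,0.8866,0.7040,0.5207,2.0522,0.7564,0.7426,0.6383
D10S1435,275,0.8969,0.7216,0.5790,2.3707,0.7891,0.7586,0.2590
D5S2500,275,0.8452,0.6386,0.4599,1.7857,0.7200,0.6946,0.3848
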