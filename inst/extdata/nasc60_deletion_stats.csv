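network,K,Dia,l,Ce,Rn,E,Vu
G0,1.1175,12,3.0467,0.0093,447,0.001258,0.0302
G1,0.9750,10,2.4462,0.0101,390,0.000944,0.0397
G2,0.8725,6,1.6998,0.0095,349,0.000726,0.0499
G3,0.9175,6,1.9530,0.0076,367,0.000849,0.0366
G4,0.9525,11,2.3965,0.0101,381,0.000859,0.0602
G5,0.9625,5,1.8720,0.0289,385,0.000919,0.0809
G6,0.9425,7,2.0107,0.0076,377,0.000811,0.0344
G7,0.8475,10,2.5515,0.0083,339,0.000804,0.0396
G8,0.9250,7,2.4457,0.0082,370,0.000892,0.0472
G9,0.8625,7,2.2134,0.0139,345,0.000784,0.0590
G10,0.9200,7,2.0985,0.0239,368,0.000863,0.0728
G11,0.9500,5,1.7365,0.0126,380,0.000806,0.0466
ave,0.9371,7.7500,2.2059,0.0125,374.8300,0.000876,0.0497
d_score,0.5785,2.7400,1.4780,4.6882,0.5800,1.07808,2.5885
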