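"g1","g2","y"
-0.4798,-1.592,0
0.8581,0.3222,1
-0.3542,0.3863,0
-0.5307,-0.0344,0
-0.0861,-0.7835,0
-0.5949,-1.131,0
3.5808,1.1427,1
0.2868,0.3808,0
1.9393,1.5231,1
-0.2545,-0.5756,0
3.6325,1.7092,1
0.5739,0.9235,0
1.8654,-0.0723,1
-0.9934,-1.6557,0
0.3907,-1.2274,1
0.0727,0.0564,0
0.8723,1.1594,1
-0.9615,-0.5146,0
0.0411,0.8177,0
0.9712,0.1123,1
2.6593,0.7962,1
0.2469,0.547,1
1.1759,0.7349,1
1.5492,0.5407,1
1.3405,0.0175,1
0.7691,-0.3722,0
-1.7551,-1.0662,0
0.6261,1.1712,1
2.9586,1.8321,1
-0.81,0.0317,0
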