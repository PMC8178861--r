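panel,icc2,icc2k
1,0.7419203747072597,0.9349545508204461
2,0.7211211445995074,0.9282069860821786
3,0.6455815202793446,0.9010647072055183
4,0.6185114956150747,0.8901889881967662
5,0.6086647727272726,0.8860628618693136
6,0.6971579643093194,0.9200655943616763
7,0.6453208739865328,0.9009631249760177
8,0.6447783811087259,0.9007515083089299
9,0.6792987188132162,0.9137249210898668
10,0.6840081187907274,0.9154204672175679
11,0.699156406748746,0.9207602690367523
12,0.753093753093753,0.9384638160329639
13,0.6722951032601637,0.9111713551385419
14,0.5913190529875986,0.8785594639865996
15,0.7349715678310317,0.9327319587628866
16,0.7297856921006313,0.9310527010962885
17,0.7525693232499516,0.938300855858034
18,0.7566386941027701,0.9395609101550231
19,0.7133605998636674,0.9256147178489298
20,0.7167024064808198,0.9267360897159406
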