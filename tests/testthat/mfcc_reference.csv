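name,value
mfcc1.mean,-12.970667806975452
mfcc1.variance,0.7074094411925277
mfcc1.skewness,0.147210097123912
mfcc1.kurtosis,2.5552231247141006
mfcc2.mean,-2.7924115510697
mfcc2.variance,0.6844153555393127
mfcc2.skewness,-0.15516581215790465
mfcc2.kurtosis,2.8062828922895378
mfcc3.mean,-2.0516932457321957
mfcc3.variance,0.7227993311528081
mfcc3.skewness,0.4027342358537759
mfcc3.kurtosis,2.553323268714391
mfcc4.mean,-0.9852424327020254
mfcc4.variance,0.841330814799565
mfcc4.skewness,-0.3208446007100426
mfcc4.kurtosis,3.290211744176874
mfcc5.mean,-0.8143826120529586
mfcc5.variance,0.6874889980892049
mfcc5.skewness,0.14224102151009627
mfcc5.kurtosis,2.821045554447563
mfcc6.mean,-0.6038176405991339
mfcc6.variance,0.6081267284585399
mfcc6.skewness,0.2202539684415804
mfcc6.kurtosis,3.0052474954251553
mfcc7.mean,-0.2820082049272272
mfcc7.variance,0.5035616207476497
mfcc7.skewness,-0.005989886697760248
mfcc7.kurtosis,2.5661227237821085
mfcc8.mean,-0.1469210470448571
mfcc8.variance,0.4732195844265087
mfcc8.skewness,0.3234388906063029
mfcc8.kurtosis,2.8538947655412463
mfcc9.mean,-0.1825307105765664
mfcc9.variance,0.524752426802962
mfcc9.skewness,0.06527152523697471
mfcc9.kurtosis,3.493503610969122
mfcc10.mean,-0.2757432443829433
mfcc10.variance,0.30804465806781894
mfcc10.skewness,-0.01698311759529061
mfcc10.kurtosis,2.4390074737595375
mfcc11.mean,-0.3289587814515099
mfcc11.variance,0.25580726294483835
mfcc11.skewness,0.450097428487063
mfcc11.kurtosis,2.7889038121889635
mfcc12.mean,-0.2258939333038118
mfcc12.variance,0.420285057585005
mfcc12.skewness,-0.13521607251050902
mfcc12.kurtosis,3.081464722523547
mfcc13.mean,-0.4560679652973696
mfcc13.variance,0.41406093585182
mfcc13.skewness,0.18870251113657172
mfcc13.kurtosis,2.9659305609599347
loge.mean,5.9809511766168235
loge.variance,0.020712823233691138
loge.skewness,-1.0933753492994658
loge.kurtosis,4.4493119768249345
mfcc1.d1.mean,0.01587886159899401
mfcc1.d1.variance,0.11738280312362859
mfcc1.d1.skewness,0.1853143458899047
mfcc1.d1.kurtosis,2.8942436628910633
mfcc2.d1.mean,0.0012533862300132136
mfcc2.d1.variance,0.0968560767257457
mfcc2.d1.skewness,0.2603118521393667
mfcc2.d1.kurtosis,2.7726149109382514
mfcc3.d1.mean,0.0010203606059806007
mfcc3.d1.variance,0.10617370885723562
mfcc3.d1.skewness,0.12109838182730527
mfcc3.d1.kurtosis,2.3515321187956824
mfcc4.d1.mean,-0.004468099253382449
mfcc4.d1.variance,0.09132509880855118
mfcc4.d1.skewness,-0.05077850626908085
mfcc4.d1.kurtosis,2.7408846988086766
mfcc5.d1.mean,-0.04282596174411221
mfcc5.d1.variance,0.06281350652760641
mfcc5.d1.skewness,-0.27040625029852444
mfcc5.d1.kurtosis,2.5086712747360984
mfcc6.d1.mean,-0.01898007182096128
mfcc6.d1.variance,0.07563749645940862
mfcc6.d1.skewness,-0.42785040372183164
mfcc6.d1.kurtosis,2.487152383817151
mfcc7.d1.mean,-0.02711947483566351
mfcc7.d1.variance,0.05610608532968937
mfcc7.d1.skewness,-0.2594402556568502
mfcc7.d1.kurtosis,2.8899007449389056
mfcc8.d1.mean,-0.00878882516775646
mfcc8.d1.variance,0.06487942824129897
mfcc8.d1.skewness,-0.4163893924932378
mfcc8.d1.kurtosis,2.528171171950344
mfcc9.d1.mean,0.010550288567849014
mfcc9.d1.variance,0.06593173080862672
mfcc9.d1.skewness,0.3315018377596997
mfcc9.d1.kurtosis,2.888538027948877
mfcc10.d1.mean,0.012147823275385841
mfcc10.d1.variance,0.04223295116798087
mfcc10.d1.skewness,-0.014683526001712344
mfcc10.d1.kurtosis,2.6601061236096863
mfcc11.d1.mean,0.0062752913860329666
mfcc11.d1.variance,0.02502522803852013
mfcc11.d1.skewness,-0.4898040309811089
mfcc11.d1.kurtosis,3.2690852288944043
mfcc12.d1.mean,0.0137716266728549
mfcc12.d1.variance,0.05156633620259023
mfcc12.d1.skewness,-0.22983796445473695
mfcc12.d1.kurtosis,2.965976080615683
mfcc13.d1.mean,0.009172290851499692
mfcc13.d1.variance,0.06262349968634487
mfcc13.d1.skewness,0.03535402631813339
mfcc13.d1.kurtosis,2.3001102891713634
loge.d1.mean,-0.003697284276277073
loge.d1.variance,0.003445152143790684
loge.d1.skewness,0.24791661889523534
loge.d1.kurtosis,2.8345654721086975
mfcc1.d2.mean,-0.01064546578312701
mfcc1.d2.variance,0.02428813698132581
mfcc1.d2.skewness,-0.1842905661860677
mfcc1.d2.kurtosis,2.7452076439449415
mfcc2.d2.mean,-0.015983465420262865
mfcc2.d2.variance,0.019287682087365976
mfcc2.d2.skewness,-0.03839777121224633
mfcc2.d2.kurtosis,2.605975149333543
mfcc3.d2.mean,-0.00202707890497895
mfcc3.d2.variance,0.02457345088040911
mfcc3.d2.skewness,-0.07787606529496315
mfcc3.d2.kurtosis,2.332768392680563
mfcc4.d2.mean,0.009871775914664833
mfcc4.d2.variance,0.01840826739377452
mfcc4.d2.skewness,0.00028406590195409335
mfcc4.d2.kurtosis,2.9192899463428787
mfcc5.d2.mean,0.006919024496496552
mfcc5.d2.variance,0.011904173481399721
mfcc5.d2.skewness,-0.102416709759118
mfcc5.d2.kurtosis,2.123088860957585
mfcc6.d2.mean,0.004493285777611982
mfcc6.d2.variance,0.016157940304700132
mfcc6.d2.skewness,0.026704955241837473
mfcc6.d2.kurtosis,2.486346171561214
mfcc7.d2.mean,0.011615961328630743
mfcc7.d2.variance,0.010523661371888223
mfcc7.d2.skewness,0.2808742846711165
mfcc7.d2.kurtosis,2.9329166566327043
mfcc8.d2.mean,0.001252461197640433
mfcc8.d2.variance,0.01518988342547393
mfcc8.d2.skewness,-0.1988106155829872
mfcc8.d2.kurtosis,2.3561741561349088
mfcc9.d2.mean,-0.011373949654589226
mfcc9.d2.variance,0.01182970347225516
mfcc9.d2.skewness,-0.38034267845788355
mfcc9.d2.kurtosis,2.8115071131546094
mfcc10.d2.mean,0.007190885240414556
mfcc10.d2.variance,0.009031774167818054
mfcc10.d2.skewness,-0.24375239233464027
mfcc10.d2.kurtosis,2.6664817173794892
mfcc11.d2.mean,0.0003990628465383893
mfcc11.d2.variance,0.005112132929492336
mfcc11.d2.skewness,-0.0037145953305473037
mfcc11.d2.kurtosis,2.844466618877708
mfcc12.d2.mean,-0.004946014801073013
mfcc12.d2.variance,0.009944007177913517
mfcc12.d2.skewness,-0.2692025653669344
mfcc12.d2.kurtosis,2.917222138711743
mfcc13.d2.mean,0.0015796646349146447
mfcc13.d2.variance,0.015054456347426366
mfcc13.d2.skewness,0.24251633089790403
mfcc13.d2.kurtosis,2.083259034784422
loge.d2.mean,0.0014626799243731233
loge.d2.variance,0.0007112095909995249
loge.d2.skewness,0.4612181292061635
loge.d2.kurtosis,2.7406891976876846
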