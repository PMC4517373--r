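id,age_at_diagnosis,psa_diag,cT,cN,cM,first_treatment,gleason_group,pT,pN,psa_post,followup_days,dead,cause,sex,diagnosis_year
P00001,68.6484503520917,10.1138039341943,,,0,surgery,intermediate,2a,,0.0534790427520103,1292,0,,male,2009
P00002,57.6337385479931,13.060551236762,3b,0,0,radiotherapy,low,,,0.482121938703589,2513,0,,male,2006
P00003,71.5558551225489,1.68238175825518,2b,,0,surgery,low,2b,0,0.0132907171926235,2422,0,,male,2006
P00004,63.2099188595178,3.23105914887609,,0,0,surgery,high,3a,0,,2493,0,,male,2006
P00005,70.4273884614263,8.25078744152612,3a,,0,hormone+chemo,intermediate,,,1.28259450806179,3423,0,,male,2004
P00006,60.330118991014,5.878589961279,1c,,0,radiotherapy,low,,,1.99965241358595,1843,0,,male,2008
P00007,67.1497051422302,14.3191397920673,,,0,,low,,,0.662468592749483,863,0,,male,2011
P00008,65.9717431370854,11.3507103570006,2a,0,0,radiotherapy,intermediate,,,0.642098421786583,2179,0,,male,2007
P00009,68.562533665371,20.5381884212586,3a,,,surgery,intermediate,3b,0,0.0479644547490246,3624,0,,male,2003
P00010,61.2157777411158,12.3483830063622,1c,0,0,surgery,low,,0,0.0286113016955199,2673,0,,male,2006
P00011,76.8770969961236,16.6363565668189,3b,,,surgery,intermediate,3b,,0.0360024777225014,2092,1,other,male,2003
P00012,65.2539370293577,34.4430702296533,2b,0,0,,intermediate,,,7.5924657644974,113,1,prostate,male,2007
P00013,65.4528743987583,27.5037147770092,2a,,0,radiotherapy,low,,,1.14997915166417,1686,0,,male,2008
P00014,70.5168351006807,2.43718026973929,2b,,0,surgery,low,2b,,,3312,0,,male,2004
P00015,72.5609382648765,10.349940548483,,0,0,,,,,,373,1,other,male,2010
P00016,70.4071634706337,4.09136263359277,3a,,0,surgery,low,3a,0,,2937,0,,male,2005
P00017,68.1425820447289,,3a,,0,surgery,low,3a,0,0.0477429374773051,650,0,,male,2011
P00018,59.2227636016396,2.78327335422257,3a,,,surgery,high,3a,0,0.229255491456403,1225,0,,male,2010
P00019,64.0416650807582,0.818957805566745,1c,0,0,surgery,low,2a,0,0.0857634383866272,1717,0,,male,2008
P00020,65.7387842224223,3.4886867410618,1c,,0,surgery,,2a,0,0.0141936048403501,2631,0,,male,2006
P00021,69.0123431835406,8.14856570565215,,,0,surgery,low,2b,0,,2116,0,,male,2007
P00022,61.3039371732252,12.875002290749,1c,0,0,surveillance+HIFU,low,,,0.321562211820433,3332,0,,male,2004
P00023,73.7520415179737,8.0620873921474,1c,,0,surveillance+HIFU,low,,,,1757,0,,male,2008
P00024,62.7125265940134,12.7122955577486,1c,,0,radiotherapy,intermediate,,,1.84324169467162,789,0,,male,2011
P00025,69.9879130120597,9.65147415229291,1c,0,0,surgery,intermediate,2a,,0.0633001638160919,3157,0,,male,2004
P00026,69.9924628946127,18.537632456061,2a,0,0,surgery,intermediate,2a,0,0.0436411616481999,2117,0,,male,2007
P00027,72.8189329578993,,,,0,radiotherapy,low,,,,1317,0,,male,2009
P00028,72.0449103952043,10.4485195135422,1c,0,0,hormone+chemo,high,,,,2228,0,,male,2007
P00029,58.7378200898121,4.52539028537968,2c,,0,radiotherapy,low,,,0.319087784815462,1722,0,,male,2008
P00030,70.6883655604018,1.72768963082549,1c,0,0,surgery,low,2a,0,0.107515846840154,2754,0,,male,2005
P00031,67.671080088407,5.6502230237483,3a,,,hormone+chemo,high,,,0.414306424611444,989,0,,male,2010
P00032,70.816292550533,9.69157035761473,,0,0,surgery,low,2a,0,,3624,0,,male,2003
P00033,72.3102941532745,13.330546473633,,,0,radiotherapy,intermediate,,,4.04423156104001,1466,1,prostate,male,2008
P00034,66.645029261354,7.04665747827214,2b,0,0,surgery,low,2c,0,0.0787177303795069,2434,0,,male,2006
P00035,66.4715880681819,17.9723558247987,1c,0,0,surveillance+HIFU,low,,,5.02834826102745,3592,0,,male,2003
P00036,70.550399839241,5.36934167482217,2a,0,0,hormone+chemo,intermediate,,,0.425120607388793,3088,1,,male,2003
P00037,63.2002197271945,13.8295770786934,2b,,0,surveillance+HIFU,intermediate,,,,3153,0,,male,2004
P00038,65.1949156267106,17.895843998606,1c,,0,surgery,low,2a,0,,2005,0,,male,2008
P00039,67.3270039135952,15.344117848326,,,0,,low,,,2.12100453345992,851,0,,male,2011
P00040,71.9298113761573,13.8887519135216,4,0,0,surgery,intermediate,4,0,0.020240727431068,3346,0,,male,2004
P00041,59.2707635835149,5.1638396767953,2a,,0,radiotherapy,intermediate,,,,3278,0,,male,2004
P00042,67.8253795477669,2.38019742809018,1c,0,0,surgery,low,2a,,0.0329681109720886,1139,0,,male,2010
P00043,70.2539556637318,7.14325861901445,1c,,0,surveillance+HIFU,low,,,,3553,0,,male,2003
P00044,61.5724350627194,1.8047088204223,1c,,,surgery,low,2b,,0.110798217580961,2289,0,,male,2007
P00045,72.6231429831212,10.1475732157579,,,,hormone+chemo,intermediate,,,,856,0,,male,2011
P00046,61.6107760946388,5.73723731594857,2c,0,0,hormone+chemo,low,,,1.0131447076723,3570,0,,male,2003
P00047,71.4911520796425,11.1684994341521,1c,,0,hormone+chemo,low,,,1.75840222923254,1049,1,,male,2003
P00048,71.569235926854,9.26495384178072,1c,0,,,intermediate,,,0.994062903241024,2187,0,,male,2007
P00049,74.505176373314,9.89311896261442,1c,,0,hormone+chemo,intermediate,,,2.22581896835373,1246,1,,male,2003
P00050,71.4858377368742,15.5053531481956,,0,0,surgery,low,2a,0,0.0970658960264336,2446,0,,male,2006
P00051,62.4363044238421,15.8631303002538,2c,,0,surgery,intermediate,2c,,0.0820705282951222,1880,0,,male,2008
P00052,74.340884999701,5.02190376212625,1c,,,surveillance+HIFU,,,,13.5855959627532,2153,0,,male,2007
P00053,59.8419326667672,7.93097253602671,1c,,0,surveillance+HIFU,intermediate,,,0.978335029131683,3307,0,,male,2004
P00054,65.0293019591955,17.0924263469589,1c,0,0,radiotherapy,low,,,,1587,0,,male,2009
P00055,61.1069133973976,7.17129307492385,3b,,0,surgery,low,4,,0.0443436272272814,2436,0,,male,2006
P00056,70.6155894670809,3.86725526525884,,,0,,intermediate,,,,2560,0,,male,2006
P00057,71.9744676752499,8.5470742345388,2c,0,,radiotherapy,low,,,0.55218154810714,2188,1,,male,2005
P00058,59.7446254352731,8.79827857228357,3a,0,0,surgery,intermediate,3a,,0.0520612178971154,2489,0,,male,2006
P00059,69.7916777104552,16.5711177360227,1c,,0,surgery,low,2a,0,0.0556714152726026,3188,0,,male,2004
P00060,67.1164689687547,6.99287652294179,1c,0,0,hormone+chemo,low,,,3.25895306163445,3052,1,other,male,2004
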