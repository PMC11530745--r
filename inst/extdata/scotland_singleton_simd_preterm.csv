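year,simd_quintile,preterm,births
2005,1,1037,12955
2006,1,1035,13119
2007,1,1090,14352
2008,1,1151,14679
2009,1,1051,14465
2010,1,1002,14725
2011,1,1038,14919
2012,1,1065,14665
2013,1,956,13950
2014,1,1047,13920
2015,1,1064,13298
2016,1,1067,13086
2017,1,1083,13002
2018,1,1087,12095
2019,1,1059,11762
2005,5,468,9164
2006,5,447,9055
2007,5,460,9272
2008,5,481,9301
2009,5,461,8873
2010,5,383,8797
2011,5,442,8683
2012,5,397,8625
2013,5,394,8442
2014,5,469,9106
2015,5,524,9054
2016,5,447,8964
2017,5,454,8388
2018,5,416,8282
2019,5,422,7824
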