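year,total,unknown_gestation,preterm,term,post_term
2005,51685,20,3361,46863,1441
2006,52709,33,3311,47832,1533
2007,55558,49,3409,50491,1609
2008,57197,56,3669,51673,1799
2009,56383,50,3476,51088,1769
2010,56377,33,3268,51526,1550
2011,56296,36,3322,51558,1380
2012,55625,63,3296,50894,1372
2013,53820,73,3235,49335,1177
2014,54596,246,3305,49913,1132
2015,53022,239,3546,48206,1031
2016,52624,414,3463,47829,918
2017,51025,272,3481,46341,931
2018,49406,29,3396,45190,791
2019,47519,12,3408,43334,765
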