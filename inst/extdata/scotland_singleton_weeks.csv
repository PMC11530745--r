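year,week,count
2005,22,4
2005,23,9
2005,24,47
2005,25,41
2005,26,50
2005,27,55
2005,28,93
2005,29,74
2005,30,93
2005,31,127
2005,32,151
2005,33,291
2005,34,393
2005,35,689
2005,36,1244
2005,37,2453
2005,38,6314
2005,39,11281
2005,40,14906
2005,41,11909
2005,42,1385
2005,43,44
2005,44,12
2010,22,6
2010,23,15
2010,24,36
2010,25,43
2010,26,56
2010,27,62
2010,28,85
2010,29,76
2010,30,85
2010,31,130
2010,32,172
2010,33,234
2010,34,388
2010,35,618
2010,36,1262
2010,37,2606
2010,38,6590
2010,39,13137
2010,40,16201
2010,41,12992
2010,42,1522
2010,43,22
2010,44,6
2015,22,6
2015,23,11
2015,24,40
2015,25,44
2015,26,43
2015,27,48
2015,28,49
2015,29,73
2015,30,82
2015,31,124
2015,32,195
2015,33,243
2015,34,441
2015,35,700
2015,36,1447
2015,37,3312
2015,38,6771
2015,39,14296
2015,40,14210
2015,41,9617
2015,42,1022
2015,43,7
2015,44,2
2019,22,6
2019,23,14
2019,24,17
2019,25,28
2019,26,46
2019,27,55
2019,28,64
2019,29,69
2019,30,83
2019,31,109
2019,32,152
2019,33,225
2019,34,394
2019,35,697
2019,36,1449
2019,37,3826
2019,38,7058
2019,39,14100
2019,40,11215
2019,41,7135
2019,42,756
2019,43,8
2019,44,1
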