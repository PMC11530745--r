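year,subcategory,spontaneous,provider_initiated,total
2005,all,2000,1360,3361
2006,all,2022,1289,3311
2007,all,2088,1320,3409
2008,all,2205,1463,3669
2009,all,2106,1370,3476
2010,all,2020,1247,3268
2011,all,2036,1285,3322
2012,all,2017,1278,3296
2013,all,1927,1307,3235
2014,all,1961,1344,3305
2015,all,2050,1493,3546
2016,all,2040,1421,3463
2017,all,2062,1417,3481
2018,all,2053,1335,3396
2019,all,2071,1327,3408
2005,moderate_late,1675,1093,2768
2006,moderate_late,1711,1019,2730
2007,moderate_late,1730,1045,2776
2008,moderate_late,1853,1189,3042
2009,moderate_late,1755,1119,2874
2010,moderate_late,1677,996,2674
2011,moderate_late,1673,1030,2703
2012,moderate_late,1688,1042,2730
2013,moderate_late,1601,1103,2704
2014,moderate_late,1602,1117,2719
2015,moderate_late,1724,1300,3026
2016,moderate_late,1706,1241,2947
2017,moderate_late,1686,1255,2943
2018,moderate_late,1685,1182,2871
2019,moderate_late,1725,1185,2917
2005,very,196,191,387
2006,very,196,188,384
2007,very,211,195,406
2008,very,235,190,425
2009,very,216,179,395
2010,very,206,170,376
2011,very,250,181,431
2012,very,218,169,387
2013,very,227,147,374
2014,very,215,167,382
2015,very,191,136,328
2016,very,216,123,339
2017,very,224,104,328
2018,very,245,104,351
2019,very,221,103,325
2005,extremely,129,76,206
2006,extremely,115,82,197
2007,extremely,147,80,227
2008,extremely,117,84,202
2009,extremely,135,72,207
2010,extremely,137,81,218
2011,extremely,113,74,188
2012,extremely,111,67,179
2013,extremely,99,57,157
2014,extremely,144,60,204
2015,extremely,135,57,192
2016,extremely,118,57,177
2017,extremely,152,58,210
2018,extremely,123,49,174
2019,extremely,125,39,166
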