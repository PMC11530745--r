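year,total,unknown_gestation,preterm,term,post_term
2005,769,1,442,326,0
2006,805,0,431,373,1
2007,867,0,458,408,1
2008,929,0,506,423,0
2009,900,1,453,446,0
2010,905,0,490,415,0
2011,827,0,465,362,0
2012,836,0,468,368,0
2013,779,0,472,307,0
2014,837,3,502,332,0
2015,790,3,509,278,0
2016,790,7,530,253,0
2017,745,3,507,235,0
2018,741,0,483,258,0
2019,696,0,442,254,0
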