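id,start_date,end_date,raw_day,raw_night,n_correct,n_false,n_excluded
1,2013-04-01,2013-04-25,2301,209,39,70,0
2,2013-04-26,2013-05-20,4093,210,88,36,0
3,2013-05-21,2013-05-31,4428,1281,88,26,3
4,2013-06-01,2013-06-12,5796,607,93,13,1
5,2013-06-13,2013-06-30,12355,1740,272,19,2
6,2013-07-01,2013-07-31,8899,468,193,6,1
7,2013-08-01,2013-08-31,4078,619,138,11,1
8,2013-09-01,2013-09-30,1642,153,103,47,0
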