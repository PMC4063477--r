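# Synthetic baseline monthly mean air temperatures (degrees C) with a
# mid-Atlantic (Chesapeake Bay, Maryland) seasonal shape, standing in for
# the mid-1980s SERC station series used to drive the warming scenarios.
# User-replaceable: any 12-value January-first monthly series can be
# supplied instead.
month	temp_c
1	1.8
2	3.1
3	7.8
4	13.3
5	18.6
6	23.3
7	25.8
8	24.9
9	21.3
10	14.9
11	9.2
12	3.7
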