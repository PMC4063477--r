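# Synthetic approximation of the seasonal availability of food for
# ground-foraging ants (understory arthropod abundance as a proxy), at 17
# approximately evenly spaced sampling days across a 365-day year
# (day 0 = Jan 1). Hand-specified to match the qualitative pattern reported
# for mature deciduous forest near SERC (Lynch, 1980s field studies): low in
# winter, rising through spring, peaking in early-mid summer, declining
# gradually through fall with availability still appreciable in early spring
# and late fall. Values are fractions of the seasonal maximum; replace with
# re-digitized data if available.
day	value
0	0.10
21	0.10
43	0.15
64	0.30
86	0.50
107	0.65
129	0.80
150	0.95
172	1.00
193	0.90
215	0.75
236	0.65
258	0.55
279	0.50
301	0.45
322	0.30
344	0.15
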