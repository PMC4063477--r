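# Synthetic approximation of the seasonal foraging intensity of
# Aphaenogaster rudis in a Maryland (SERC) deciduous-forest ant community,
# on the first day of each month (day 0 = Jan 1, 365-day year).
# Hand-specified to match the qualitative pattern reported in field studies
# (Lynch and co-workers, late 1970s/1980s): the longest active season of
# the guild (roughly March through November), unimodal with an early/mid-
# summer peak and substantial activity on both the spring and fall
# shoulders, no winter activity. Values are fractions of the seasonal
# maximum; replace with re-digitized data if available.
day	value
0	0.00
31	0.00
59	0.15
90	0.45
120	0.75
151	0.95
181	1.00
212	0.90
243	0.75
273	0.50
304	0.20
334	0.00
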