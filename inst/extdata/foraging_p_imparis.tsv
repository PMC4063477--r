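# Synthetic approximation of the seasonal foraging intensity of
# Prenolepis imparis (the "winter ant") in a Maryland (SERC)
# deciduous-forest ant community, on the first day of each month
# (day 0 = Jan 1, 365-day year). Hand-specified to match the qualitative
# pattern reported in field studies (Lynch and co-workers, late
# 1970s/1980s): a cool-season forager (roughly October through May) with
# spring and fall peaks, near-complete summer aestivation, and continued
# moderate winter activity. Values are fractions of the seasonal maximum;
# replace with re-digitized data if available.
day	value
0	0.35
31	0.50
59	0.90
90	1.00
120	0.45
151	0.10
181	0.02
212	0.05
243	0.30
273	0.85
304	0.80
334	0.50
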