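# Synthetic approximation of the seasonal foraging intensity of
# Nylanderia faisonensis in a Maryland (SERC) deciduous-forest ant
# community, on the first day of each month (day 0 = Jan 1, 365-day year).
# Hand-specified to match the qualitative pattern reported in field studies
# (Lynch and co-workers, late 1970s/1980s): a mid/late-summer peak with an
# active season (roughly May through October) nested inside the broader
# A. rudis season, intense foraging July-October, negligible winter
# activity. Values are fractions of the seasonal maximum; replace with
# re-digitized data if available.
day	value
0	0.00
31	0.00
59	0.00
90	0.05
120	0.30
151	0.70
181	1.00
212	0.95
243	0.80
273	0.45
304	0.05
334	0.00
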