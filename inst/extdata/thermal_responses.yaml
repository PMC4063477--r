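# Synthetic per-species thermal performance curves (Gaussian in
# temperature) used to rescale baseline foraging under uniform warming.
# The original species-specific foraging-temperature relationships are not
# available in a reusable form, so these parameters are qualitative
# stand-ins, chosen so that warming (i) advances and intensifies the spring
# activity of the cool-adapted P. imparis, (ii) depresses mid-summer
# foraging of the heat-susceptible A. rudis, and (iii) mildly reduces the
# intensity of N. faisonensis foraging without shifting its timing (broad
# response). Fully user-replaceable.
#
# t_opt:   thermal optimum, degrees C
# breadth: Gaussian standard deviation, degrees C
species:
  n_faisonensis:
    t_opt: 16.0
    breadth: 12.0
  a_rudis:
    t_opt: 21.0
    breadth: 6.5
  p_imparis:
    t_opt: 12.0
    breadth: 7.0
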