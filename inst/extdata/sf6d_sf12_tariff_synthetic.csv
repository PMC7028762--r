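# tariff: SYNTHETIC stand-in preference tariff for the SF-6D (SF-12 variant)
# The licensed Sheffield preference weights are not redistributable; this file
# reproduces the published model STRUCTURE only: additive level decrements on
# six dimensions (pf, rl, sf, pain, mh, vit), monotone within dimension, plus
# a single 'most' penalty applied when any dimension is at its most severe
# level. Floor (worst state) = 0.345. Replace with licensed coefficients for
# substantive use; the loader accepts any file with this layout.
# utility = 1 - sum(decrement[dimension, level]) - most * any(level == max)
dimension,level,decrement
pf,1,0
pf,2,0.035
pf,3,0.075
rl,1,0
rl,2,0.035
rl,3,0.040
rl,4,0.060
sf,1,0
sf,2,0.040
sf,3,0.050
sf,4,0.060
sf,5,0.085
pain,1,0
pain,2,0.030
pain,3,0.050
pain,4,0.080
pain,5,0.140
mh,1,0
mh,2,0.045
mh,3,0.060
mh,4,0.090
mh,5,0.140
vit,1,0
vit,2,0.030
vit,3,0.040
vit,4,0.060
vit,5,0.090
most,1,0.065
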