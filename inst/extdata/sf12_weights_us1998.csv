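# instrument: SF-12 version 1
# weights: US 1998 norm-based PCS-12 / MCS-12 indicator regression weights
# constants: pcs 56.57706, mcs 60.75781 (rows item=_constant)
# raw item coding: gh1 1=excellent..5=poor; pf02,pf04 1=limited a lot,2=a little,3=not limited;
# rp2,rp3,re2,re3 1=yes,2=no; bp2 1=not at all..5=extremely; mh3,vt2 1=all of the time..6=none;
# mh4 1=all of the time..6=none; sf2 1=all of the time..5=none of the time
item,level,pcs_weight,mcs_weight
_constant,0,56.57706,60.75781
gh1,1,0,0
gh1,2,-1.31872,-0.06064
gh1,3,-3.02396,0.03482
gh1,4,-5.56461,-0.16891
gh1,5,-8.37399,-1.71175
pf02,1,-7.23216,3.93115
pf02,2,-3.45555,1.86840
pf02,3,0,0
pf04,1,-6.24397,2.68282
pf04,2,-2.73557,1.43103
pf04,3,0,0
rp2,1,-4.61617,1.44060
rp2,2,0,0
rp3,1,-5.51747,1.66968
rp3,2,0,0
re2,1,3.04365,-6.82672
re2,2,0,0
re3,1,2.32091,-5.69921
re3,2,0,0
bp2,1,0,0
bp2,2,-3.80130,0.90384
bp2,3,-6.50522,1.49384
bp2,4,-8.38063,1.76691
bp2,5,-11.25544,1.48619
mh3,1,0,0
mh3,2,0.66514,-1.94949
mh3,3,1.36689,-4.09842
mh3,4,2.37241,-6.31121
mh3,5,2.90426,-7.92717
mh3,6,3.46638,-10.19085
vt2,1,0,0
vt2,2,-0.42251,-0.92057
vt2,3,-1.14387,-1.65178
vt2,4,-1.61850,-3.29805
vt2,5,-2.02168,-4.88962
vt2,6,-2.44706,-6.02409
mh4,1,4.61446,-16.15395
mh4,2,3.41593,-10.77911
mh4,3,2.34247,-8.09914
mh4,4,1.28044,-4.59055
mh4,5,0.41188,-1.95934
mh4,6,0,0
sf2,1,-0.33682,-6.29724
sf2,2,-0.94342,-8.26066
sf2,3,-0.18043,-5.63286
sf2,4,0.11038,-3.13896
sf2,5,0,0
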