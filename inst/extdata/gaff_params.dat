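; GAFF-style parameter table for ffforge topologies.
; Lennard-Jones values follow the GAFF convention: rmin/2 in Angstrom,
; epsilon in kcal/mol. Covers every atom type the packaged rule set emits.

[ atomtypes ]
; type  mass     rmin_half  epsilon
c    12.011  1.9080  0.0860
c1   12.011  1.9080  0.0860
c2   12.011  1.9080  0.0860
c3   12.011  1.9080  0.1094
ca   12.011  1.9080  0.0860
cc   12.011  1.9080  0.0860
cd   12.011  1.9080  0.0860
ce   12.011  1.9080  0.0860
cf   12.011  1.9080  0.0860
cp   12.011  1.9080  0.0860
cq   12.011  1.9080  0.0860
cx   12.011  1.9080  0.1094
cy   12.011  1.9080  0.1094
h1    1.008  1.3870  0.0157
h2    1.008  1.2870  0.0157
h3    1.008  1.1870  0.0157
h4    1.008  1.4090  0.0150
h5    1.008  1.3590  0.0150
ha    1.008  1.4590  0.0150
hc    1.008  1.4870  0.0157
hn    1.008  0.6000  0.0157
ho    1.008  0.0000  0.0000
hp    1.008  0.6000  0.0157
hs    1.008  0.6000  0.0157
hx    1.008  1.1000  0.0157
n    14.007  1.8240  0.1700
n1   14.007  1.8240  0.1700
n2   14.007  1.8240  0.1700
n3   14.007  1.8240  0.1700
n4   14.007  1.8240  0.1700
na   14.007  1.8240  0.1700
nb   14.007  1.8240  0.1700
nc   14.007  1.8240  0.1700
nd   14.007  1.8240  0.1700
nh   14.007  1.8240  0.1700
no   14.007  1.8240  0.1700
o    15.999  1.6612  0.2100
oh   15.999  1.7210  0.2104
op   15.999  1.6837  0.1700
os   15.999  1.6837  0.1700
p3   30.974  2.1000  0.2000
p5   30.974  2.1000  0.2000
s    32.060  2.0000  0.2500
s4   32.060  2.0000  0.2500
s6   32.060  2.0000  0.2500
sh   32.060  2.0000  0.2500
ss   32.060  2.0000  0.2500
f    18.998  1.7500  0.0610
cl   35.450  1.9480  0.2650
br   79.904  2.0200  0.3200

[ dihedraltypes ]
; barrier height (kcal/mol) keyed on the central-bond type pair;
; X is a wildcard, the X X row is the global fallback
ca  ca  3.625
ca  cp  3.625
cc  cc  4.000
cc  na  1.700
cc  nb  4.800
ce  ce  1.000
ce  c2  6.650
c   n   2.500
c   c3  0.156
c   oh  2.300
c   os  2.700
c3  c3  0.156
c3  n3  0.300
c3  n4  0.156
c3  nh  0.300
c3  oh  0.160
c3  os  0.383
c3  sh  0.250
c3  ss  0.333
c3  ca  0.000
X   c1  0.000
X   X   0.300
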