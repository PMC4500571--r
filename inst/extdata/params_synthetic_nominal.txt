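# Synthetic nominal kinetic parameter set for the B-lymphoid commitment
# network. Discovered with the package's bifurcation-search tooling under
# the qualitative constraints of the canonical commitment switch:
#  - irreversible bistable EBF1-activation response at T_ZNF521 = 0
#    (left limit point on the negative T_EBF1 semiaxis),
#  - reversible bistable response at T_ZNF521 = 0.12,
#  - LMPP attractor: FLT3 & ZNF521 high, EBF1/PAX5/CD19 low;
#    pro-B attractor: the reverse.
# Units: production/degradation rates 1/s; interaction strengths
# dimensionless.
a0 = 0.01
a1 = 10
a2 = 1
a3 = 0.2
a4 = 10
a5 = 0.02
a6 = 0.02
a7 = 0.05
a8 = 0.05
a9 = 1
a10 = 0.1
a11 = 0.02
a12 = 0.02
b0 = 0.05
b1 = 6.75
b2 = 2
b3 = 1
b4 = 0.5
c0 = 0.01
c1 = 0.5
c2 = 0.1
c3 = 0.5
d0 = 0.01
d1 = 0.3
e0 = 0.1
e1 = 2
e2 = 2
e3 = 1
e4 = 2
e5 = 1
e6 = 1
f0 = 0.01
f1 = 0.3
f2 = 0.2
f3 = 0.1
g0 = 0.1
g1 = 1
g2 = 2
h0 = 0.1
h1 = 1
i0 = 0.1
j0 = 0.01
j1 = 0.2
mu1 = 0.1
mu2 = 0.1
mu3 = 0.1
mu4 = 0.1
mu5 = 0.1
mu6 = 0.1
mu7 = 0.1
mu8 = 0.1
mu9 = 0.1
mu10 = 0.1
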