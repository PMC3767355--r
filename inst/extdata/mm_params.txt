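# macroconf molecular-mechanics parameter set, version 1
# Generic MM2-like literature-typical constants; see the package vignette.
#
# Atom classes: C  sp3 carbon | C2 sp2 carbon | O  ester/ether oxygen
#               O2 carbonyl oxygen | H hydrogen | FE tricarbonyliron pseudo-atom
#
# stretch <classA> <classB> <order> <ks kcal/mol/A^2> <r0 A>      E = ks (r-r0)^2
# bend    <central class>   <kb kcal/mol/rad^2> <theta0 deg>      E = kb (th-th0)^2
# torsion <classB> <classC> <order> <V1> <V2> <V3 kcal/mol>       3-term cosine, per quadruple
# vdw     <class> <eps kcal/mol> <rstar A>                        LJ 6-12, r*ij = ri*+rj*
# dipole  <class+> <class-> <order> <mu Debye>                    points from + to - atom
version 1
stretch C  C  1 317 1.526
stretch C  C2 1 317 1.501
stretch C2 C2 1 350 1.465
stretch C2 C2 2 480 1.337
stretch C2 O2 2 570 1.225
stretch C2 O  1 360 1.355
stretch C  O  1 310 1.430
stretch C  H  1 330 1.095
stretch C2 H  1 350 1.083
stretch C2 FE coord 100 2.25
bend C  50 110.0
bend C2 60 120.0
bend O  70 111.0
torsion C  C  1 0 0    0.30
torsion C  C2 1 0 0    0.15
torsion C2 C2 1 0 1.25 0
torsion C2 C2 2 0 12.0 0
torsion C2 O  1 0 5.00 0
torsion C  O  1 0 0    0.40
vdw C  0.044 1.90
vdw C2 0.044 1.94
vdw O  0.050 1.74
vdw O2 0.050 1.74
vdw H  0.047 1.50
vdw FE 0.100 2.80
dipole C2 O2 2 2.30
dipole C2 O  1 1.00
dipole C  O  1 1.20
dipole C  C2 1 0.30
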