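# Buffer-gas interaction parameters, version 1.
#
# Each gas is modelled as a single isotropic pseudo-atom.  Per-element 12-6
# Lennard-Jones parameters follow the published trajectory-method
# parameterization lineage: the N2 set descends from the MOBCAL-style
# nitrogen parameterization for ion mobility (per-element eps/sigma tuned
# against drift-tube data); the He set is the original trajectory-method
# helium parameterization.  sigma values were converted to the position of
# the 12-6 minimum, r_min = 2^(1/6) sigma; well depths converted from meV
# to kcal/mol (1 eV = 23.060548 kcal/mol).
#
# gas properties: mass (Da), polarizability (A^3), hs_radius: effective
# hard-sphere half-radius of the gas used by the projection approximation
# (half the smallest per-element r_min of the gas table).
#
# epsilon_kcal: well depth (kcal/mol); r_min_A: pair minimum distance (A).
gas,element,epsilon_kcal,r_min_A,gas_mass,gas_polarizability,gas_hs_radius
N2,H,0.0189096,2.671451,28.0134,1.710,1.335726
N2,C,0.1072315,3.928726,28.0134,1.710,1.335726
N2,N,0.1111515,3.794033,28.0134,1.710,1.335726
N2,O,0.0936258,3.412400,28.0134,1.710,1.335726
N2,S,0.1277550,3.928726,28.0134,1.710,1.335726
He,H,0.0149894,2.671451,4.002602,0.205,1.335726
He,C,0.0309011,3.415717,4.002602,0.205,1.335726
He,N,0.0309011,3.415717,4.002602,0.205,1.335726
He,O,0.0309011,3.415717,4.002602,0.205,1.335726
He,S,0.0311318,3.928726,4.002602,0.205,1.335726
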