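# Backbone united-sphere parameters. Diameters in Angstrom, masses in CH3
# (15 amu) units; masses are published values. near_factor scales hard
# cores of non-bonded local neighbour pairs.
parameter	value
diam_nh	3.3
diam_ca	3.7
diam_co	3.5
mass_nh	0.999
mass_ca	0.866
mass_co	1.863
near_factor	0.75
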