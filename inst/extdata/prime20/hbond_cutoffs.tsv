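# Auxiliary hydrogen-bond distance cutoffs (A) for donor residue i and
# acceptor residue j: N_i-Ca_j, N_i-N_(j+1), C_j-Ca_i, C_j-C_(i-1).
# Published values for both the parallel-preference and original sets.
mode	n_ca	n_n	c_ca	c_c
parallel_preference	5.1	4.54	4.96	4.58
original	5	4.74	4.86	4.83
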