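# Coupling (grab) multiplier (GM) lookup for the Revised NIOSH Lifting Equation.
# coupling: hand-to-object coupling quality. v_band: hand height at origin.
# table_version: RNLE-1991
coupling,v_band,gm
good,v_lt_75,1.00
good,v_ge_75,1.00
fair,v_lt_75,0.95
fair,v_ge_75,1.00
poor,v_lt_75,0.90
poor,v_ge_75,0.90
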