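# Frequency multiplier (FM) lookup for the Revised NIOSH Lifting Equation.
# lifts_per_min: tabulated lifting frequency (1/min). Intermediate frequencies
#   are resolved by rounding UP to the next tabulated row (conservative).
# duration: short (<=1 h), medium (<=2 h), long (<=8 h) work duration.
# v_band: vertical height of the hands at lift origin, below or at/above 75 cm.
# fm: dimensionless multiplier in [0, 1].
# table_version: RNLE-1991
lifts_per_min,duration,v_band,fm
0.2,short,v_lt_75,1.00
0.2,short,v_ge_75,1.00
0.2,medium,v_lt_75,0.95
0.2,medium,v_ge_75,0.95
0.2,long,v_lt_75,0.85
0.2,long,v_ge_75,0.85
0.5,short,v_lt_75,0.97
0.5,short,v_ge_75,0.97
0.5,medium,v_lt_75,0.92
0.5,medium,v_ge_75,0.92
0.5,long,v_lt_75,0.81
0.5,long,v_ge_75,0.81
1,short,v_lt_75,0.94
1,short,v_ge_75,0.94
1,medium,v_lt_75,0.88
1,medium,v_ge_75,0.88
1,long,v_lt_75,0.75
1,long,v_ge_75,0.75
2,short,v_lt_75,0.91
2,short,v_ge_75,0.91
2,medium,v_lt_75,0.84
2,medium,v_ge_75,0.84
2,long,v_lt_75,0.65
2,long,v_ge_75,0.65
3,short,v_lt_75,0.88
3,short,v_ge_75,0.88
3,medium,v_lt_75,0.79
3,medium,v_ge_75,0.79
3,long,v_lt_75,0.55
3,long,v_ge_75,0.55
4,short,v_lt_75,0.84
4,short,v_ge_75,0.84
4,medium,v_lt_75,0.72
4,medium,v_ge_75,0.72
4,long,v_lt_75,0.45
4,long,v_ge_75,0.45
5,short,v_lt_75,0.80
5,short,v_ge_75,0.80
5,medium,v_lt_75,0.60
5,medium,v_ge_75,0.60
5,long,v_lt_75,0.35
5,long,v_ge_75,0.35
6,short,v_lt_75,0.75
6,short,v_ge_75,0.75
6,medium,v_lt_75,0.50
6,medium,v_ge_75,0.50
6,long,v_lt_75,0.27
6,long,v_ge_75,0.27
7,short,v_lt_75,0.70
7,short,v_ge_75,0.70
7,medium,v_lt_75,0.42
7,medium,v_ge_75,0.42
7,long,v_lt_75,0.22
7,long,v_ge_75,0.22
8,short,v_lt_75,0.60
8,short,v_ge_75,0.60
8,medium,v_lt_75,0.35
8,medium,v_ge_75,0.35
8,long,v_lt_75,0.18
8,long,v_ge_75,0.18
9,short,v_lt_75,0.52
9,short,v_ge_75,0.52
9,medium,v_lt_75,0.30
9,medium,v_ge_75,0.30
9,long,v_lt_75,0.00
9,long,v_ge_75,0.15
10,short,v_lt_75,0.45
10,short,v_ge_75,0.45
10,medium,v_lt_75,0.26
10,medium,v_ge_75,0.26
10,long,v_lt_75,0.00
10,long,v_ge_75,0.13
11,short,v_lt_75,0.41
11,short,v_ge_75,0.41
11,medium,v_lt_75,0.00
11,medium,v_ge_75,0.23
11,long,v_lt_75,0.00
11,long,v_ge_75,0.00
12,short,v_lt_75,0.37
12,short,v_ge_75,0.37
12,medium,v_lt_75,0.00
12,medium,v_ge_75,0.21
12,long,v_lt_75,0.00
12,long,v_ge_75,0.00
13,short,v_lt_75,0.00
13,short,v_ge_75,0.34
13,medium,v_lt_75,0.00
13,medium,v_ge_75,0.00
13,long,v_lt_75,0.00
13,long,v_ge_75,0.00
14,short,v_lt_75,0.00
14,short,v_ge_75,0.31
14,medium,v_lt_75,0.00
14,medium,v_ge_75,0.00
14,long,v_lt_75,0.00
14,long,v_ge_75,0.00
15,short,v_lt_75,0.00
15,short,v_ge_75,0.28
15,medium,v_lt_75,0.00
15,medium,v_ge_75,0.00
15,long,v_lt_75,0.00
15,long,v_ge_75,0.00
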