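# 10-peak subcutaneous fat spectrum, triglyceride model with
# chain length CL = 17.4, double bonds ndb = 2.73, methylene-interrupted
# double bonds nmidb = 0.76 (human subcutaneous adipose composition).
# shift_ppm is relative to the water resonance at 4.70 ppm
# (negative = lower frequency than water). rel_amplitude sums to 1.
shift_ppm	rel_amplitude	assignment
0.59	0.05409154	olefinic -CH=CH-
0.49	0.00990688	glycerol CH
-0.40	0.01981375	glycerol CH2 (4.30 ppm)
-0.60	0.01981375	glycerol CH2 (4.10 ppm)
-1.95	0.01505845	diallylic =CH-CH2-CH=
-2.46	0.05944125	alpha-carboxyl -CH2-COO
-2.68	0.07806618	alpha-olefinic -CH2-CH=
-3.10	0.05944125	beta-carboxyl -CH2-CH2-COO
-3.40	0.59520507	methylene -(CH2)n-
-3.80	0.08916188	methyl -CH3
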