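# Synthetic example of a 3DNA-style base-pair-step parameter table.
# Values mimic the step-parameter pattern of a strongly kinked
# protein-bound dodecamer (one TT step with large positive roll and
# undertwist); they are illustrative, not measured from any structure.
step   shift  slide   rise   tilt   roll  twist
AC     -0.2    0.1    3.3    -1.0    2.0   34.5
CA      0.1   -0.3    3.4     2.0    5.0   33.0
AA      0.0    0.0    3.3     0.5    1.0   35.0
AA      0.1    0.2    3.3    -0.5    0.0   34.0
AT      0.0   -0.1    3.4     1.0    3.0   32.5
TT      0.3    0.5    3.6     5.0   60.0   24.3
TG     -0.1    0.2    3.4    -2.0    4.0   33.5
GA      0.0    0.0    3.3     1.5    2.5   34.8
AT      0.1   -0.2    3.3     0.0    1.0   34.3
TA      0.0    0.1    3.4    -1.0    6.0   33.0
AA     -0.1    0.0    3.3     0.5    1.5   34.6
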