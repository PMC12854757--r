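# Anharmonic roll/twist stiffness set for the central AT step of the
# Drew-Dickerson dodecamer (CGCGAATTCGCG), obtained by stepwise fitting of
# the cubic/quartic surface to a biased all-atom free-energy landscape.
# Coefficients are on the conventional printed scales (quadratic x 1e-2,
# cubic x 1e-4, quartic x 1e-5; kBT and degrees); the scale factors are
# applied when the file is loaded.
quadratic:
  a2: 5.6
  c2: 9.7
  g: 1.6
  scale: 1.0e-2
cubic:
  a3: 0.2
  c3: 10.5
  b: -2.5
  d: -1.6
  scale: 1.0e-4
quartic:
  a4: -4.3
  c4: -4.3
  h: -8.7
  scale: 1.0e-5
fit_cutoff_quadratic: 3
fit_cutoff_full: 7
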