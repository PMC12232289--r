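# Population two-compartment C-peptide kinetic parameters, Van Cauter-type
# standardization by clinical status. The plasma impulse response is
#   h(t) = (1/vd) * [f * exp(-k_short t) + (1-f) * exp(-k_long t)],
# k = ln(2)/halflife (minutes). The distribution volume is regressed on
# body-surface area: vd = vd_slope_l_per_m2 * BSA + vd_intercept_l (litres).
version: 1
statuses:
  normal:
    frac_short: 0.76
    halflife_short_min: 4.95
    halflife_long_min: 29.2
    vd_slope_l_per_m2: 1.11
    vd_intercept_l: 2.04
  obese:
    frac_short: 0.78
    halflife_short_min: 4.55
    halflife_long_min: 32.0
    vd_slope_l_per_m2: 1.11
    vd_intercept_l: 2.04
  diabetic:
    frac_short: 0.78
    halflife_short_min: 4.52
    halflife_long_min: 27.0
    vd_slope_l_per_m2: 1.11
    vd_intercept_l: 2.04
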