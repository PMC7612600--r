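# Built-in true-coefficient scenario library.
#
# All scenarios share a 20% baseline response on control for biomarker-negative
# patients (alpha = logit(0.2)) and zero biomarker main effects.  The linked
# treatment-biomarker interaction magnitude (2.1 on the log-odds scale) was
# calibrated by bisection so that every allocation strategy reaches at least
# 80% power for the linked hypothesis H0(1,1) at the default design
# (N = 400, prevalences 0.30/0.25/0.30/0.25); constrained randomisation is the
# weakest strategy and anchors the calibration.  The "some benefit" main
# effect (0.30) gives deliberately modest power.  Every value can be
# overridden: edit a copy of this file, or pass `overrides` to
# scenario_library().
#
# delta keys are "k,l": the interaction of treatment k with biomarker l.
# Scenarios 5-7 are intentionally absent: the library mirrors the nine rows
# of the reported power table.
K: 4
baseline_response: 0.2
scenarios:
  scenario1:
    label: All treatments have the same effect as control
  scenario2:
    label: T1 works in B1-positive patients only
    delta: {"1,1": 2.1}
  scenario3:
    label: T1 works in B2-positive patients only
    delta: {"1,2": 2.1}
  scenario4:
    label: T1 has a detrimental effect in B1-positive patients
    delta: {"1,1": -2.1}
  scenario8:
    label: T1 benefits B1-positive and harms B2-positive patients
    delta: {"1,1": 2.1, "1,2": -2.1}
  scenario9:
    label: T1 benefits B2-positive and harms B1-positive patients
    delta: {"1,2": 2.1, "1,1": -2.1}
  scenario10:
    label: T1 harms B1-positive patients, T2 benefits B1-positive patients
    delta: {"1,1": -2.1, "2,1": 2.1}
  scenario11:
    label: T1 provides some benefit for all patients
    beta: {"1": 0.30}
  scenario12:
    label: T1 provides some benefit for all and works in B1-positive patients
    beta: {"1": 0.30}
    delta: {"1,1": 2.1}
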