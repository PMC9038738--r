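# Two-phase mechanical stimulation protocol for dynamic constructs:
# one conditioning day (slow 0->10% ramp over 7 h, 17 h rest) followed by
# one training day (3 cycles of 10 stretches in 10 min at 5% strain).
# Extend days/repeats for the full 5 + 7 day schedule.
phases:
  - type: ramp
    start_percent: 0
    end_percent: 10
    duration_s: 25200
  - type: rest
    duration_s: 61200
  - type: cyclic
    strain_percent: 5
    stretches_per_cycle: 10
    cycle_duration_s: 600
    cycles_per_day: 3
    days: 1
params:
  membrane_diameter_mm: 22
  initial_elastic_modulus_MPa: 1
dt_s: 1
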