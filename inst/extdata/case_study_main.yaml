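# Canadian residential-care case study: main parameter tables.
#
# Provenance (per block):
#   group_transition   : published cohort studies of cognitive/mobility decline
#                        in nursing-home residents, expressed per 2-month cycle
#   mortality          : published nursing-home mortality registry, weighted for
#                        sex, per 2-month cycle, with 95% CIs
#   initial            : group mix from published German nursing-home surveys;
#                        care-stage and skin-health mix from the baseline of an
#                        8-week two-arm Canadian nursing-home trial of a
#                        sensor-based digital bladder diary
#   cs_transition      : 8-week care-stage movement observed in the two trial
#                        arms, applied per model cycle
#   shl_given_cs       : per-cycle skin-health mixture per care stage, trial
#                        arms combined with published dermatitis-severity data
#   event_rates        : per-cycle probabilities from published incidence data
#                        (conventional arm); DHT reductions from expert opinion
#   utilities          : EQ-5D-5L group baselines and decrement magnitudes
#                        derived from published valuation studies (decrements
#                        stored as non-negative magnitudes to subtract)
#   task_minutes/staff : manufacturer time-and-motion data on file plus expert
#                        opinion (G6 staffing); treatment application assumed
meta:
  label: canadian-residential-case-study
  currency: CAD
  price_year: 2020
settings:
  discount_rate: 0.05
  start_age: 86
  max_cycles: 240
  survival_epsilon: 1.0e-06
  included_groups: [G2, G3, G4, G5, G6]
  group_change_cs: independent
initial:
  group: {G2: 0.21, G3: 0.46, G4: 0.19, G5: 0.09, G6: 0.05}
  cs: {CS1: 0.16, CS2: 0.47, CS3: 0.37}
  shl: {SHL1: 0.89, SHL2: 0.07, SHL3: 0.02, SHL4: 0.02, SHL5: 0.01}
group_transition:   # rows G2..G6, cols G2..G6, per 2-month cycle
  G2: [0.935, 0.063, 0.002, 0.000, 0.000]
  G3: [0.000, 0.914, 0.064, 0.022, 0.000]
  G4: [0.000, 0.000, 0.393, 0.585, 0.022]
  G5: [0.000, 0.000, 0.000, 0.978, 0.022]
  G6: [0.000, 0.000, 0.000, 0.000, 1.000]
cs_shift:           # care-stage shift for group-movers under "shift" composition
  p_stay: 0.10
  p_worsen: 0.90
mortality:          # probability of death per 2-month cycle
  bands: ["65-74", "75-84", "85-94", "95+"]
  classes: [G1, G4, other]      # "other" covers G2, G3, G5, G6
  mean:
    - [0.069, 0.036, 0.055]
    - [0.064, 0.048, 0.056]
    - [0.069, 0.068, 0.069]
    - [0.087, 0.102, 0.092]
  lo:
    - [0.066, 0.033, 0.054]
    - [0.063, 0.047, 0.055]
    - [0.068, 0.067, 0.068]
    - [0.082, 0.094, 0.088]
  hi:
    - [0.071, 0.038, 0.057]
    - [0.066, 0.050, 0.057]
    - [0.071, 0.070, 0.070]
    - [0.092, 0.109, 0.097]
cs_transition:      # rows CS1..CS3, cols CS1..CS3, per cycle (printed rounded)
  conventional:
    CS1: [0.38, 0.63, 0.00]
    CS2: [0.10, 0.45, 0.45]
    CS3: [0.06, 0.50, 0.44]
  dht:
    CS1: [0.25, 0.75, 0.00]
    CS2: [0.23, 0.68, 0.09]
    CS3: [0.06, 0.35, 0.59]
shl_given_cs:       # rows CS1..CS3, cols SHL1..SHL5, per cycle
  conventional:
    CS1: [1.000, 0.000, 0.000, 0.000, 0.000]
    CS2: [0.972, 0.018, 0.004, 0.004, 0.003]
    CS3: [0.875, 0.075, 0.016, 0.016, 0.013]
  dht:
    CS1: [1.000, 0.000, 0.000, 0.000, 0.000]
    CS2: [0.972, 0.018, 0.004, 0.004, 0.003]
    CS3: [1.000, 0.000, 0.000, 0.000, 0.000]
event_rates:        # per-cycle probabilities; fractures only toileting-related
  conventional:
    fracture_g2_g4: 0.0027
    fracture_g5_g6: 0.0000
    uti: 0.0577
    constipation: 0.0894
    pu1: 0.2940
    pu2: 0.0680
    pu3: 0.0074
    pu4: 0.0154
  dht:
    fracture_g2_g4: 0.0026
    fracture_g5_g6: 0.0000
    uti: 0.0543
    constipation: 0.0787
    pu1: 0.2917
    pu2: 0.0675
    pu3: 0.0073
    pu4: 0.0153
utilities:
  group: {G1: 0.80, G2: 0.70, G3: 0.64, G4: 0.54, G5: 0.30, G6: 0.30}
  d_cs: {CS1: 0.000, CS2: 0.014, CS3: 0.030}
  d_shl: {SHL1: 0.000, SHL2: 0.033, SHL3: 0.033, SHL4: 0.035, SHL5: 0.037}
  d_event:
    fracture: 0.121
    uti: 0.090
    constipation: 0.030
    pu1: 0.000
    pu2: 0.037
    pu3: 0.037
    pu4: 0.037
task_minutes:       # average minutes per task occurrence per staff member, G2..G6
  product_check:        [3.20, 4.10, 4.10, 4.10, 4.10]
  product_change:       [6.60, 10.20, 10.20, 10.20, 10.20]
  toileting_assistance: [9.50, 11.70, 11.70, 11.70, 11.70]
  leakage_change:       [7.40, 9.10, 9.10, 9.10, 9.10]
  shl5_treatment:       [1.00, 1.00, 1.00, 1.00, 1.00]
staff_per_task:     # number of staff required per task occurrence, G2..G6
  product_check:        [1.00, 1.00, 1.00, 1.00, 1.00]
  product_change:       [1.30, 1.30, 1.30, 1.30, 2.00]
  toileting_assistance: [1.30, 1.30, 1.30, 1.30, 2.00]
  leakage_change:       [1.30, 1.30, 1.30, 1.30, 2.00]
  shl5_treatment:       [1.00, 1.00, 1.00, 1.00, 1.00]
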