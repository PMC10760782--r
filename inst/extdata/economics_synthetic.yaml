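# SYNTHETIC economics fixture.
#
# The case study's unit costs and resource-use frequencies come from
# supplementary data files that are not redistributed here. This file is a
# stand-in with plausible CAD-2020 values so the full cost pathway (labour,
# products, hygiene, disposal, care consequences, skin treatment, technology)
# is exercisable end to end. Every value below is a documented placeholder,
# NOT a transcription of the case study's cost inputs; cost results obtained
# with this file are illustrative only. Effect-side results do not use it.
synthetic: true
wage_formal_per_min: 0.75        # blended care-staff cost incl. overhead, CAD/min
wage_informal_per_min: 0.25      # opportunity-cost valuation of informal care
informal_share: 0.0              # residential setting: all care is formal
task_freq_per_day:               # task occurrences per resident-day, CS1..CS3
  conventional:                  # (group-invariant placeholder)
    product_check:        [2.00, 3.00, 4.00]
    product_change:       [2.00, 3.00, 4.00]
    toileting_assistance: [4.00, 2.50, 0.50]
    leakage_change:       [0.20, 0.30, 0.50]
  dht:                           # sensor-informed plans: fewer checks/changes,
    product_check:        [1.50, 2.00, 2.50]   # more assisted toileting
    product_change:       [1.80, 2.70, 3.60]
    toileting_assistance: [4.50, 3.00, 0.80]
    leakage_change:       [0.15, 0.25, 0.40]
products:                        # one representative product mix per care stage
  price_per_piece:               # CAD, CS1..CS3
    conventional: [0.35, 0.55, 0.85]
    dht:          [0.35, 0.55, 0.85]
  daily_count:                   # mean pieces per resident-day, CS1..CS3
    conventional: [3.00, 3.50, 4.00]
    dht:          [2.70, 3.10, 3.40]
  dry_weight_kg:  [0.06, 0.09, 0.13]
  absorbency_ml:  [1400, 1900, 2600]   # Rothwell value per piece
hygiene_cost_per_application:    # perineal hygiene consumables per change
  conventional: 0.10
  dht: 0.25                      # better products assumed after training
disposal_tariff_per_kg: 0.30
event_costs:                     # CAD per occurrence
  fracture: 12000
  uti: 320
  constipation: 180
  pu1: 120
  pu2: 1200
  pu3: 5000
  pu4: 10000
technology_cost_per_person_year: # acquisition incl. software and sensor briefs
  conventional: 0
  dht: 250
shl5_treatment:
  duration_days: 7               # one treated episode per cycle with severe IAD
  unit_cost_per_application: 1.50
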