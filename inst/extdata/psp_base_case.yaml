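# Base-case model configuration: moderate-to-large primary spontaneous
# pneumothorax in a stable adult ED patient. Costs are 2022 USD national
# averages (CMS); probabilities are pooled randomized-trial estimates;
# ranges are the one-way sensitivity-analysis ranges.
probabilities:
  p_obs:              {base: 0.846, low: 0.769, high: 0.896}   # initial success, observation only
  p_na:               {base: 0.657, low: 0.635, high: 0.952}   # initial success, needle aspiration
  p_valve:            {base: 0.769, low: 0.530, high: 0.910}   # initial success, small-bore chest tube + one-way valve
  p_suction:          {base: 0.756, low: 0.630, high: 0.990}   # initial success, small-bore chest tube to suction
costs:
  ed_visit:               {code: "99285",  base: 1097.43,  low: 877.94,   high: 1316.92}   # ED visit, high complexity
  chest_xray:             {code: "71045",  base: 94.00,    low: 75.20,    high: 112.80}
  needle_aspiration:      {code: "32554",  base: 683.00,   low: 546.40,   high: 819.60}    # pleural aspiration w/o imaging
  pleural_catheter:       {code: "32556",  base: 1931.00,  low: 1544.80,  high: 2317.20}   # small-bore chest tube w/o imaging
  pneumothorax_admission: {code: "DRG201", base: 28858.84, low: 23087.07, high: 34630.61}  # admission w/o complication
  vats_admission:         {code: "DRG165", base: 86135.69, low: 69908.55, high: 103362.83} # VATS admission w/o complication
utilities:
  baseline:                {base: 1.00, low: 0.90, high: 1.00}  # baseline state of health
  resolved_psp:            {base: 0.92, low: 0.85, high: 0.95}  # resolved pneumothorax
  invasive_lung_procedure: {base: 0.83, low: 0.78, high: 0.88}  # post-VATS long-term state
settings:
  discount_rate:   {base: 0.03, low: 0.01, high: 0.05}  # per year
  wtp: 50000                                            # USD per QALY
  age:             {base: 25, low: 15, high: 35}        # years
  life_expectancy: {base: 78, low: 60, high: 82}        # years
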