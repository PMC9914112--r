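# Runtime configuration for the dosing engine.
# scoop_grams: mass of one scoop of formula powder (g); all doses are
#   expressed in whole scoops of this size.
# energy_tolerance / protein_tolerance: relative band around the daily
#   target within which delivered energy/protein raises no warning flag.
# feeds_per_day_by_band: bottle feeds per day for each monthly age band.
# plasma_bands: therapeutic plasma ranges (umol/L) used by the default
#   adjustment rule tree. NON-AUTHORITATIVE defaults; a treating metabolic
#   dietitian must supply clinic-specific values.
scoop_grams: 5
energy_tolerance: 0.10
protein_tolerance: 0.10
feeds_per_day_by_band:
  "1": 8
  "2": 8
  "3": 8
  "4": 6
  "5": 6
  "6": 6
plasma_bands:
  leucine:
    low_max: 75
    high_min: 200
  isoleucine:
    low_max: 200
    high_min: 400
  valine:
    low_max: 200
    high_min: 400
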