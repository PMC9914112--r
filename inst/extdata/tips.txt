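General care tips for caregivers of infants with MSUD
(placeholder guidance; confirm every item with your metabolic team)

* Keep every scheduled appointment with the metabolic dietitian; plasma
  branched-chain amino acid levels change quickly in the first six months
  and allowances are typically reassessed every 2-4 weeks.
* Never change the formula brand, scoop size or number of feeds without
  consulting the metabolic team first.
* Use the scoop supplied with the formula tin and level it off; heaped or
  packed scoops can deliver substantially more amino acids than intended.
* During illness, fever or poor feeding, contact the metabolic team
  immediately: catabolic stress can raise plasma leucine even when intake
  is controlled.
* Record every feed (scoops given, volume taken, time) so the team can
  reconstruct actual intake between visits.
* Watch for early warning signs of decompensation: unusual drowsiness,
  irritability, poor feeding, vomiting, or a maple-syrup odor in urine or
  ear wax, and seek urgent care if they appear.
* Store prepared formula refrigerated and discard unused prepared feeds
  after 24 hours.
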