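# msudbuddy

Knowledge-based daily formula dosing for infants (0–6 months) with maple
syrup urine disease (MSUD).

MSUD is an inborn error of metabolism in which the three branched-chain
amino acids (BCAAs) — leucine, isoleucine and valine — cannot be catabolized,
so their dietary intake must be strictly capped while protein, energy and
fluid needs are still met. Caregivers feed a mix of ordinary **commercial**
infant formula (the only BCAA source) and BCAA-free **medical** metabolic
formula, and struggle to translate per-day nutrient limits into scoops of
powder. `msudbuddy` does that translation: given an infant's age, weight and
plasma BCAA panel plus a formula preference, it produces a scoop-discretized
daily feeding plan that provably never exceeds any BCAA allowance.

## What it computes

For age band *a* (months 1–6), weight *w* (kg), per-kg allowance table *T*
and formula compositions *C* (commercial) and *M* (medical, per 100 g
powder):

1. **Daily allowance**: `A_x = T[a, x] · w` for x ∈ {leu, ile, val (mg),
   protein (g), energy (kcal), fluid (mL)}.
2. **Plasma adjustment**: a single-classification ripple-down-rules (RDR)
   tree maps the plasma panel to an optional multiplicative tightening of
   BCAA caps (default tree: level above the configured therapeutic band →
   factor 0.5 plus a consult-dietitian flag; non-clinical placeholder).
3. **Allocation**: commercial grams
   `g_C = min_b A_b / (C_b / 100)` over the BCAAs the formula contains
   (the argmin is the *limiting nutrient*); medical grams fill the protein
   gap, `g_M = max(0, (A_protein − g_C · C_protein/100) / (M_protein/100))`.
4. **Scoop discretization** (5 g scoops by default): commercial scoops =
   `⌊g_C / s⌋` (round *down* — BCAA safety), medical scoops = round-half-up
   of the protein remainder; scoops and the fluid allowance are split evenly
   over the band's feeds. Delivered protein/energy outside ±10% of target
   raises a flag.

The RDR engine itself is generic: deterministic inference over an
exception/alternative rule tree, and incremental knowledge acquisition that
attaches each new rule at the exact point a case was misclassified and
rejects any rule that would change a stored cornerstone case's conclusion.
Trees persist as JSON.

## Worked example

```r
library(msudbuddy)
kb <- load_kb()
rec <- recommend(patient_profile(age_months = 3, weight_kg = 5),
                 plasma_panel(leucine = 80, isoleucine = 17, valine = 55),
                 formula_selection("Similac", "Ketonex-1"), kb)
rec
```

```
Recommended daily intake
  leucine       462.5 mg
  isoleucine    280.0 mg
  valine        322.5 mg
  protein       15.80 g
  energy        600.0 kcal
  fluid         500.0 mL

Feeding plan (5g scoops, 8 feeds/day)
  commercial Similac: 8 scoops (40 g)
  medical    Ketonex-1: 15 scoops (75 g)
  water: 500 mL/day
  delivered: leu 431.6 mg, ile 229.2 mg, val 256.4 mg, protein 15.58 g, energy 570.4 kcal
  limiting nutrient: leucine
```

Reading: the band-3 per-kg allowances times 5 kg give the daily targets;
leucine is the tightest constraint on Similac (462.5 mg ÷ 10.79 mg/g allows
42.86 g, floored to 8 scoops = 40 g delivering 431.6 mg ≤ 462.5 mg), and
Ketonex-1 tops the protein up to 15.58 g of the 15.8 g target. Delivered
energy (570.4 kcal) sits inside the ±10% band around 600 kcal, so no flag is
raised.

The same pipeline is available from a shell via the installed launcher
script (`inst/scripts/msud-buddy`):

```sh
msud-buddy recommend --age-months 3 --weight-kg 5 \
  --leucine 80 --isoleucine 17 --valine 55 \
  --commercial Similac --medical Ketonex-1 --json
msud-buddy allowance --patient patient.json
msud-buddy kb show
msud-buddy rdr trace --tree rules.json --attr plasma_leucine=250
msud-buddy tips
```

## Scope and caveats

The plasma therapeutic bands and the default adjustment tree are
configuration placeholders, not clinical guidance; the knowledge base covers
six formulas and ages 0–6 months only, and breast-milk composition is out of
scope. This software does not replace a metabolic dietitian.
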