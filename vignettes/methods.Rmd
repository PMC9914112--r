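---
title: "Methods: RDR inference and scoop-discretized MSUD formula dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RDR inference and scoop-discretized MSUD formula dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msudbuddy)
```

## The problem

In maple syrup urine disease (MSUD) the branched-chain amino acids (BCAAs)
leucine, isoleucine and valine cannot be catabolized, so an infant's daily
intake of each must stay under an age- and weight-dependent cap while
protein, energy and fluid needs are still met. In the first six months the
only intake is formula powder: ordinary *commercial* formula carries intact
protein and hence BCAAs; *medical* metabolic formula is BCAA-free. The
practical question a caregiver faces every day is therefore: *how many
scoops of each powder, in how many feeds, with how much water?* This
package answers it deterministically and auditable-y, with a hard safety
guarantee on the BCAA side.

## The knowledge base

Two tables and one configuration file, shipped as plain text under
`inst/extdata/` and validated on every load:

* **Per-kg daily allowances** over six monthly age bands: isoleucine,
  leucine, valine (mg/kg/day), protein (g/kg/day), energy (kcal/kg/day,
  constant 120) and fluid (mL/kg/day, constant 100). The table is
  interpreted *per kilogram* because only then do the printed magnitudes
  make physiological sense for an infant (120 kcal and 100 mL per day total
  would not), and because the dose computation explicitly scales by weight.
  The allowance pattern is not monotone between bands 3 and 4 (leucine
  92.5 → 56 mg/kg); the table is shipped exactly as verified by the
  knowledge-engineering source and not "corrected".
* **Formula compositions** per 100 g of powder for three commercial
  (Nan 1, Similac, Aptamil) and three medical (Ketonex-1, Anamix, Comida)
  products. Loading enforces that every medical formula is exactly
  BCAA-free — that property is what makes the two-formula allocation below
  well-posed. Nan 1's BCAA values are an order of magnitude below the other
  commercial products; they too are shipped as verified, and the dosing
  consequences (very large BCAA-capped doses, flagged protein overshoot)
  fall out of the arithmetic rather than being special-cased.
* **Configuration**: scoop mass (default 5 g — one level spoonful, the
  standard dose unit), protein and energy tolerances (default ±10%), feeds
  per day by band (8 for bands 1–3, 6 for bands 4–6; a common clinical
  rhythm, made explicit here because no authoritative feed count exists in
  the source material), and plasma therapeutic bands (leucine 75–200
  µmol/L, isoleucine and valine 200–400 µmol/L). The plasma bands are
  **configuration placeholders, not clinical guidance**: they exist so the
  rule mechanism is exercisable, and every deployment is expected to
  override them.

Ages are mapped to bands by `ceiling(age_months)` clamped to `[1, 6]`, with
age 0 (birth) in band 1. Fractional ages are accepted because allowances
are reassessed every few weeks in practice; any boundary rule is equally
defensible, and ceiling is the conservative choice early in a band (it
picks the band the infant is growing *into* for protein, while BCAA caps
remain enforced exactly).

## The ripple-down-rules engine

Plasma-driven adjustments are expressed as a single-classification
ripple-down-rules (RDR) tree: a binary tree whose nodes carry a condition
(a conjunction of atomic comparisons), a conclusion, and the *cornerstone
case* that motivated the rule. Inference walks from the root: condition
true → descend into the *except* child (a refinement); false → descend into
the *alt* child (an alternative); return the conclusion of the last node
whose condition held. The root's condition is always true, so inference is
total, and the fired path is bounded by the node count, so it terminates.

Knowledge acquisition (`rdr_add_rule`) attaches a new rule exactly where
inference on the misclassified case stopped — as except child if that
node's condition held, else as alt child — and is accepted only if (a) the
new condition holds on its own cornerstone and (b) replaying *every*
previously registered cornerstone yields its original conclusion. A
conflict is a hard rejection naming the conflicting cornerstone: the
expert must supply a discriminating condition, the engine never invents
one. This is what makes incremental maintenance safe: past behaviour is
never silently changed.

Semantics choices worth stating explicitly:

* The condition language is conjunctions of
  `{==, !=, <, <=, >, >=, present, absent}` atoms — no disjunction, no
  arithmetic. Every rule the nutrition tables imply is expressible, and
  the restricted language keeps acquisition checkable.
* Any comparison against an attribute the case lacks evaluates `FALSE`
  (only the `absent` operator sees absence positively). Partial cases thus
  fall through to default conclusions instead of erroring.
* Trees persist as a strict JSON dialect (unknown keys rejected, child ids
  verified); a reloaded tree infers identically, which the tests check by
  replaying random cases.

The default adjustment tree is deliberately minimal: one exception rule per
BCAA that halves that amino acid's allowance and raises a
`consult_dietitian` flag when its plasma level exceeds the configured upper
band, checked in the order leucine, isoleucine, valine (leucine first,
reflecting its primacy in MSUD management; single classification means only
the first exceeded BCAA fires). Whether plasma values should modulate
allowances multiplicatively, by band substitution, or only via referral is
genuinely open; the multiplicative factor with a mandatory flag is the
most conservative mechanism that keeps the pipeline total, and factors are
constrained to `(0, 1]` so a rule tree can only ever *tighten* a BCAA cap.

## Allocation and discretization

Given the (possibly adjusted) daily allowance `A`, commercial composition
`C` and medical composition `M` (per 100 g):

* **Commercial grams** `g_C = min_b A_b / (C_b/100)` over the BCAAs with
  `C_b > 0`; the argmin is the limiting nutrient (ties broken
  leucine > isoleucine > valine). A hypothetical BCAA-free commercial
  powder is instead capped by the protein target and nothing is limiting.
* **Medical grams** `g_M = max(0, (A_protein − g_C·C_protein/100) /
  (M_protein/100))`.

Two formulas give two degrees of freedom, and they are spent on the BCAA
cap and the protein target. Energy is a *check*, not a third allocation
variable: delivered energy outside ±10% of target raises a flag for the
dietitian rather than perturbing the dose. Fluid is passed through as the
water used to reconstitute the feeds (powder displacement volume is
ignored) and split evenly.

Discretization into whole scoops of mass `s` is deliberately asymmetric:

* commercial scoops `= ⌊g_C / s⌋` — rounding **down**, so delivered BCAAs
  can never exceed the allowance. This is the package's hard safety
  invariant, property-tested over thousands of random patients.
* medical scoops = round-half-up of the protein still uncovered by the
  *rounded* commercial dose. Medical powder is BCAA-free, so the only cost
  of rounding is protein/energy error, which the tolerance flags monitor.

The scoop pair this policy produces coincides with an independent
brute-force search over all integer scoop pairs: among pairs respecting
every BCAA cap, take the largest commercial count, then the medical count
minimizing the absolute protein error (half-ties rounding up). The test
suite and the acceptance script both run that grid search as an oracle and
require exact agreement. The grid extends to 240 commercial × 70 medical
scoops so it contains the whole feasible region even for Nan 1's very low
BCAA content.

Numerical details: the floor uses a `1e-9` slack so an allocation that is
an exact scoop multiple up to floating-point error is not knocked down a
scoop; feasibility comparisons in the oracle carry the same slack; a plan
of zero total scoops against a positive protein requirement is an
infeasibility error advising dietitian referral, not a silent empty plan.

## Validation inputs and what they show

Randomized tests draw patients uniformly: age 0–6 months, weight 2–10 kg,
plasma leucine 0–500 µmol/L and isoleucine/valine 0–600 µmol/L — spanning
both in-range panels and panels that trigger every adjustment rule — and
cross them with all nine commercial × medical pairs. This emulates the
*coverage* of the input space, not the joint distribution of a real clinic
population (real age–weight pairs are correlated, real panels cluster
around treatment targets). Passing therefore shows the arithmetic and the
safety invariant hold everywhere in the supported envelope; it says nothing
about clinical outcomes, and the default plasma bands and adjustment
factors remain placeholders for a clinic's own rules. Problem sizes: 1000
patients × 9 pairs in the acceptance suite and script, 40 spot-checks plus
structural properties (weight monotonicity, medical-only zero-BCAA
delivery, scale invariance of the rounding under (w, s) → (2w, 2s)) in the
unit tests.

## Known limitations

* Six formulas, six age bands, 0–6 months; no breast-milk composition, no
  solid food, no sick-day protocols.
* Height is recorded but used by no dosing rule.
* The energy check can flag but not repair a plan; with Aptamil's low
  protein density, protein-driven doses can overshoot energy, and with
  Nan 1 the BCAA cap admits doses that overshoot protein — both surface as
  flags for a human, by design.
* The adjustment mechanism (multiplicative factors on BCAA caps) is one of
  several defensible readings of how plasma levels should modulate intake;
  it is isolated behind `apply_plasma_adjustment` so a clinic can replace
  the tree without touching the allocation arithmetic.
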