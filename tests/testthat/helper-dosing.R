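# Brute-force grid-search oracle for the scoop-discretized allocation:
# enumerate every integer (commercial, medical) scoop pair on a grid wide
# enough to contain the whole feasible region (Nan 1's very low BCAA content
# admits >170 commercial scoops at the heaviest weights), keep the pairs
# whose delivered BCAAs respect the (possibly adjusted) daily allowance,
# then pick lexicographically: largest commercial count (the BCAA-bearing
# powder is pushed to its safe maximum), smallest
# |delivered protein - target|, half-ties to the larger medical count.
SCOOP_GRID <- expand.grid(c = 0:240, m = 0:70)

oracle_scoops <- function(allowance, commercial, medical, scoop_grams) {
  g <- SCOOP_GRID
  cg <- g$c * scoop_grams
  feas <- cg * commercial$leucine_mg_per_100g / 100 <=
            allowance$leucine_mg + 1e-9 &
          cg * commercial$isoleucine_mg_per_100g / 100 <=
            allowance$isoleucine_mg + 1e-9 &
          cg * commercial$valine_mg_per_100g / 100 <=
            allowance$valine_mg + 1e-9
  g <- g[feas, , drop = FALSE]
  protein <- (g$c * commercial$protein_g_per_100g +
              g$m * medical$protein_g_per_100g) * scoop_grams / 100
  err <- abs(protein - allowance$protein_g)
  best <- order(-g$c, err, -g$m)[1L]
  c(commercial = g$c[best], medical = g$m[best])
}

rand_patient <- function() {
  list(profile = patient_profile(round(stats::runif(1, 0, 6), 2),
                                 round(stats::runif(1, 2, 10), 2)),
       panel = plasma_panel(round(stats::runif(1, 0, 500), 1),
                            round(stats::runif(1, 0, 600), 1),
                            round(stats::runif(1, 0, 600), 1)))
}
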