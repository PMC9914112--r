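#' @title Dosing core: allowance scaling, allocation, scoop discretization
#' @description
#' The pipeline that turns a validated patient record into a daily feeding
#' plan: (1) scale the per-kg allowance for the age band by body weight;
#' (2) let the RDR tree adjust allowances from the plasma panel; (3) allocate
#' commercial formula up to the tightest BCAA limit and fill the remaining
#' protein requirement with BCAA-free medical formula; (4) discretize both
#' doses into whole 5 g scoops, rounding the BCAA-bearing commercial dose
#' *down* (safety) and the medical dose to the nearest scoop, then split the
#' day's scoops and reconstitution water over the feeds.
#'
#' The hard safety invariant throughout: delivered leucine, isoleucine and
#' valine never exceed the (possibly adjusted) daily allowance.
#' @name recommender
NULL

BCAAS <- c("leucine", "isoleucine", "valine")

#' Scale a per-kg allowance to a daily allowance
#'
#' @param per_kg one-row allowance record from [lookup_allowance()].
#' @param weight_kg body weight in kg, > 0.
#' @return a `daily_allowance` list: `leucine_mg`, `isoleucine_mg`,
#'   `valine_mg` (daily caps), `protein_g`, `energy_kcal`, `fluid_ml` (daily
#'   targets), plus `age_band` and `adjustment_applied` (NULL until an RDR
#'   adjustment fires).
#' @examples
#' kb <- load_kb()
#' scale_allowance(lookup_allowance(kb, 3), 5)$leucine_mg  # 462.5
#' @export
scale_allowance <- function(per_kg, weight_kg) {
  stopifnot(is.data.frame(per_kg), nrow(per_kg) == 1L)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L ||
      !is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be a positive number", call. = FALSE)
  }
  structure(list(
    leucine_mg = per_kg$leucine_mg_per_kg * weight_kg,
    isoleucine_mg = per_kg$isoleucine_mg_per_kg * weight_kg,
    valine_mg = per_kg$valine_mg_per_kg * weight_kg,
    protein_g = per_kg$protein_g_per_kg * weight_kg,
    energy_kcal = per_kg$energy_kcal_per_kg * weight_kg,
    fluid_ml = per_kg$fluid_ml_per_kg * weight_kg,
    age_band = per_kg$age_band,
    adjustment_applied = NULL,
    flags = character(0)), class = "daily_allowance")
}

#' Default plasma-adjustment rule tree
#'
#' A deliberately conservative starter tree, NOT a clinically validated
#' protocol: the default rule keeps the table allowances unchanged; one
#' exception rule per BCAA halves that amino acid's allowance and raises a
#' consult-dietitian flag when its plasma level exceeds the configured
#' `high_min` threshold. Leucine is checked first, reflecting its primacy in
#' MSUD management; this is single-classification, so only the first
#' exceeded BCAA's rule fires. Clinics are expected to grow their own tree
#' with [rdr_add_rule()] and ship it via `save_tree()`.
#'
#' @param config the `config` element of a [load_kb()] knowledge base.
#' @return an [rdr_tree()].
#' @export
default_rdr_tree <- function(config = load_kb()$config) {
  pb <- config$plasma_bands
  tree <- rdr_tree(rdr_conclusion(
    "default_limits", explanation = "plasma panel raises no adjustment"))
  reduce_rule <- function(bcaa) {
    list(
      case = rdr_case(stats::setNames(
        list(pb[[bcaa]]$high_min * 2), paste0("plasma_", bcaa))),
      condition = rdr_condition(
        rdr_atom(paste0("plasma_", bcaa), ">", pb[[bcaa]]$high_min)),
      conclusion = rdr_conclusion(
        paste0("reduce_", bcaa),
        payload = stats::setNames(list(0.5), paste0(bcaa, "_factor")),
        explanation = paste0("plasma ", bcaa, " above ", pb[[bcaa]]$high_min,
                             " umol/L: halve the ", bcaa,
                             " allowance and consult the dietitian")))
  }
  for (bcaa in BCAAS) {
    r <- reduce_rule(bcaa)
    tree <- rdr_add_rule(tree, r$case, r$condition, r$conclusion)
  }
  tree
}

#' Apply a plasma-driven RDR adjustment to an allowance
#'
#' Runs RDR inference on the panel; if the winning conclusion's payload
#' carries multiplicative `<bcaa>_factor` entries, each named BCAA allowance
#' is multiplied by its factor, `adjustment_applied` records the conclusion
#' label and a `consult_dietitian` flag is raised. The default conclusion
#' leaves the allowance untouched. Factors must lie in (0, 1]: the rule tree
#' may only tighten BCAA caps, never relax them.
#'
#' @param allowance a `daily_allowance` from [scale_allowance()].
#' @param panel a validated [plasma_panel()].
#' @param tree an [rdr_tree()]; defaults to [default_rdr_tree()].
#' @return the (possibly adjusted) `daily_allowance`, with attribute
#'   `rdr_path` recording the fired node ids.
#' @export
apply_plasma_adjustment <- function(allowance, panel,
                                    tree = default_rdr_tree()) {
  stopifnot(inherits(allowance, "daily_allowance"),
            inherits(panel, "plasma_panel"), inherits(tree, "rdr_tree"))
  case <- rdr_case(list(plasma_leucine = panel$leucine,
                        plasma_isoleucine = panel$isoleucine,
                        plasma_valine = panel$valine))
  res <- rdr_infer(tree, case)
  payload <- res$conclusion$payload
  adjusted <- FALSE
  for (bcaa in BCAAS) {
    f <- payload[[paste0(bcaa, "_factor")]]
    if (is.null(f)) next
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
      stop("rule tree misconfigured: ", bcaa, "_factor must lie in (0, 1], ",
           "got ", f, call. = FALSE)
    }
    field <- paste0(bcaa, "_mg")
    if (f < 1) {
      allowance[[field]] <- allowance[[field]] * f
      adjusted <- TRUE
    }
  }
  if (adjusted) {
    allowance$adjustment_applied <- res$conclusion$label
    allowance$flags <- union(allowance$flags, "consult_dietitian")
  }
  attr(allowance, "rdr_path") <- res$fired_path
  attr(allowance, "rdr_explanation") <- res$conclusion$explanation
  allowance
}

#' Allocate formula grams under BCAA and protein constraints
#'
#' The commercial (BCAA-bearing) dose is pushed up to the tightest BCAA
#' limit: `commercial_grams = min_b allowance_b / (commercial_b / 100)` over
#' the BCAAs the formula actually contains; the limiting nutrient is the
#' argmin (ties broken leucine > isoleucine > valine). If the commercial
#' formula contains no BCAA at all, the dose is capped by the protein target
#' instead and no nutrient is limiting. The medical (BCAA-free) dose then
#' fills whatever protein the commercial dose leaves uncovered.
#'
#' @param allowance a `daily_allowance` (after any adjustment).
#' @param commercial one-row commercial composition from [lookup_formula()],
#'   or `NULL` for a medical-only plan.
#' @param medical one-row medical composition, or `NULL` for a
#'   commercial-only plan.
#' @return an `allocation_result` list: `commercial_grams`, `medical_grams`
#'   (both pre-rounding g/day) and `limiting_nutrient` (`"leucine"`,
#'   `"isoleucine"`, `"valine"` or `"none"`).
#' @export
allocate <- function(allowance, commercial, medical) {
  stopifnot(inherits(allowance, "daily_allowance"))
  if (!is.null(commercial) && commercial$category != "commercial") {
    stop("allocate: '", commercial$name, "' is not a commercial formula",
         call. = FALSE)
  }
  if (!is.null(medical) && medical$category != "medical") {
    stop("allocate: '", medical$name, "' is not a medical formula",
         call. = FALSE)
  }
  limiting <- "none"
  if (is.null(commercial)) {
    commercial_grams <- 0
  } else {
    per_g <- c(leucine = commercial$leucine_mg_per_100g,
               isoleucine = commercial$isoleucine_mg_per_100g,
               valine = commercial$valine_mg_per_100g) / 100
    caps <- c(leucine = allowance$leucine_mg,
              isoleucine = allowance$isoleucine_mg,
              valine = allowance$valine_mg)
    active <- per_g > 0
    if (any(active)) {
      ratios <- caps[active] / per_g[active]
      # ties broken in the fixed order leucine > isoleucine > valine,
      # which names(ratios) already follows
      limiting <- names(ratios)[which.min(ratios)]
      commercial_grams <- min(ratios)
    } else {
      commercial_grams <- allowance$protein_g /
        (commercial$protein_g_per_100g / 100)
    }
  }
  protein_gap <- allowance$protein_g -
    commercial_grams * (if (is.null(commercial)) 0 else
      commercial$protein_g_per_100g / 100)
  if (is.null(medical)) {
    medical_grams <- 0
  } else {
    if (medical$protein_g_per_100g <= 0) {
      stop("infeasible: medical formula '", medical$name,
           "' supplies no protein", call. = FALSE)
    }
    medical_grams <- max(0, protein_gap / (medical$protein_g_per_100g / 100))
  }
  structure(list(commercial_grams = commercial_grams,
                 medical_grams = medical_grams,
                 limiting_nutrient = limiting),
            class = "allocation_result")
}

round_half_up <- function(x) floor(x + 0.5)

delivered_nutrients <- function(c_grams, m_grams, commercial, medical) {
  pick <- function(comp, col) if (is.null(comp)) 0 else comp[[col]]
  list(
    leucine_mg = c_grams * pick(commercial, "leucine_mg_per_100g") / 100 +
      m_grams * pick(medical, "leucine_mg_per_100g") / 100,
    isoleucine_mg = c_grams * pick(commercial, "isoleucine_mg_per_100g") / 100 +
      m_grams * pick(medical, "isoleucine_mg_per_100g") / 100,
    valine_mg = c_grams * pick(commercial, "valine_mg_per_100g") / 100 +
      m_grams * pick(medical, "valine_mg_per_100g") / 100,
    protein_g = c_grams * pick(commercial, "protein_g_per_100g") / 100 +
      m_grams * pick(medical, "protein_g_per_100g") / 100,
    energy_kcal = c_grams * pick(commercial, "energy_kcal_per_100g") / 100 +
      m_grams * pick(medical, "energy_kcal_per_100g") / 100)
}

#' Discretize an allocation into a scoop-based feeding plan
#'
#' Doses are expressed in whole scoops of `config$scoop_grams` (default 5 g,
#' one spoonful). The commercial count rounds DOWN
#' (`floor(commercial_grams / scoop)`) so BCAA delivery can never exceed the
#' allowance; the medical count is then recomputed from the protein the
#' rounded commercial dose actually covers and rounded half-up to the
#' nearest scoop -- medical powder is BCAA-free, so only the protein/energy
#' tolerances are at stake. Water equals the daily fluid allowance; scoops
#' are split as evenly as integers allow across the band's feeds, remainders
#' going to the earliest feeds. Flags are raised when delivered protein or
#' energy falls outside `target * (1 +/- tolerance)`.
#'
#' @param result an `allocation_result` from [allocate()].
#' @param allowance the `daily_allowance` the allocation served.
#' @param commercial,medical composition rows (either may be `NULL`,
#'   matching the allocation).
#' @param config the knowledge-base `config` list.
#' @return a `feeding_plan` list; see [recommend()] for the full shape.
#' @export
discretize <- function(result, allowance, commercial, medical,
                       config = load_kb()$config) {
  stopifnot(inherits(result, "allocation_result"),
            inherits(allowance, "daily_allowance"))
  scoop <- config$scoop_grams
  if (!is.numeric(scoop) || scoop <= 0) {
    stop("config: scoop_grams must be > 0", call. = FALSE)
  }
  commercial_scoops <- if (is.null(commercial)) 0L else
    as.integer(floor(result$commercial_grams / scoop + 1e-9))
  medical_scoops <- if (is.null(medical)) 0L else {
    covered <- commercial_scoops * scoop *
      (if (is.null(commercial)) 0 else commercial$protein_g_per_100g / 100)
    need_g <- max(0, allowance$protein_g - covered) /
      (medical$protein_g_per_100g / 100)
    as.integer(round_half_up(need_g / scoop))
  }
  if (commercial_scoops + medical_scoops == 0L && allowance$protein_g > 0) {
    stop("infeasible plan: the BCAA limits leave no room for even one scoop ",
         "of the selected formulas; refer the patient to the metabolic ",
         "dietitian", call. = FALSE)
  }
  feeds <- config$feeds_per_day_by_band[[as.character(allowance$age_band)]]
  if (is.null(feeds)) feeds <- 6L
  feeds <- as.integer(feeds)

  split_even <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + as.integer(seq_len(k) <= extra)
  }
  per_feed <- data.frame(
    feed = seq_len(feeds),
    commercial_scoops = split_even(commercial_scoops, feeds),
    medical_scoops = split_even(medical_scoops, feeds),
    water_ml = rep(allowance$fluid_ml / feeds, feeds))

  delivered <- delivered_nutrients(commercial_scoops * scoop,
                                   medical_scoops * scoop,
                                   commercial, medical)
  flags <- allowance$flags
  ptol <- config$protein_tolerance
  etol <- config$energy_tolerance
  if (delivered$protein_g < allowance$protein_g * (1 - ptol)) {
    flags <- union(flags, "protein_below_tolerance")
  } else if (delivered$protein_g > allowance$protein_g * (1 + ptol)) {
    flags <- union(flags, "protein_above_tolerance")
  }
  if (delivered$energy_kcal < allowance$energy_kcal * (1 - etol)) {
    flags <- union(flags, "energy_below_tolerance")
  } else if (delivered$energy_kcal > allowance$energy_kcal * (1 + etol)) {
    flags <- union(flags, "energy_above_tolerance")
  }
  structure(list(
    commercial_scoops = commercial_scoops,
    medical_scoops = medical_scoops,
    scoop_grams = scoop,
    water_ml = allowance$fluid_ml,
    feeds_per_day = feeds,
    per_feed = per_feed,
    delivered = delivered,
    limiting_nutrient = result$limiting_nutrient,
    flags = flags), class = "feeding_plan")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (is.null(attr(e, "stage"))) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      attr(e, "stage") <- name
    }
    stop(e)
  })
}

#' Recommend a daily feeding plan
#'
#' End-to-end pipeline: allowance lookup -> weight scaling -> plasma-driven
#' RDR adjustment -> BCAA/protein allocation -> scoop discretization. Errors
#' from any stage are tagged with the stage name.
#'
#' @param profile a [patient_profile()].
#' @param panel a [plasma_panel()] (validated here).
#' @param selection a [formula_selection()] (validated here).
#' @param kb a knowledge base from [load_kb()].
#' @param tree an [rdr_tree()] of plasma-adjustment rules; `NULL` uses
#'   [default_rdr_tree()].
#' @return a `msud_recommendation` list with `allowance` (the daily intake
#'   report), `plan` (the `feeding_plan`), the resolved `formulas`, and
#'   `rdr_path`.
#' @examples
#' kb <- load_kb()
#' rec <- recommend(patient_profile(3, 5),
#'                  plasma_panel(80, 17, 55),
#'                  formula_selection("Similac", "Ketonex-1"), kb)
#' rec$plan$commercial_scoops  # 8
#' @export
recommend <- function(profile, panel, selection, kb = load_kb(),
                      tree = NULL) {
  stopifnot(inherits(profile, "patient_profile"), inherits(kb, "msud_kb"))
  stage("validate", validate_panel(panel))
  resolved <- stage("validate", validate_selection(selection, kb))
  if (is.null(tree)) tree <- default_rdr_tree(kb$config)
  per_kg <- stage("allowance_lookup", lookup_allowance(kb, profile$age_months))
  allowance <- stage("scale", scale_allowance(per_kg, profile$weight_kg))
  allowance <- stage("plasma_adjustment",
                     apply_plasma_adjustment(allowance, panel, tree))
  alloc <- stage("allocate",
                 allocate(allowance, resolved$commercial, resolved$medical))
  plan <- stage("discretize",
                discretize(alloc, allowance, resolved$commercial,
                           resolved$medical, kb$config))
  structure(list(allowance = allowance, plan = plan,
                 formulas = list(
                   commercial = resolved$commercial$name %||% NULL,
                   medical = resolved$medical$name %||% NULL),
                 rdr_path = attr(allowance, "rdr_path"),
                 rdr_explanation = attr(allowance, "rdr_explanation")),
            class = "msud_recommendation")
}

#' Render a recommendation as a plain list ready for JSON output
#'
#' @param rec a `msud_recommendation`.
#' @return an unclassed nested list matching the documented plan schema.
#' @export
recommendation_to_list <- function(rec) {
  stopifnot(inherits(rec, "msud_recommendation"))
  a <- rec$allowance
  p <- rec$plan
  list(
    allowance = list(
      leucine_mg = a$leucine_mg, isoleucine_mg = a$isoleucine_mg,
      valine_mg = a$valine_mg, protein_g = a$protein_g,
      energy_kcal = a$energy_kcal, fluid_ml = a$fluid_ml,
      age_band = a$age_band,
      adjustment_applied = a$adjustment_applied),
    plan = list(
      commercial = list(name = rec$formulas$commercial,
                        scoops = p$commercial_scoops,
                        grams = p$commercial_scoops * p$scoop_grams),
      medical = list(name = rec$formulas$medical,
                     scoops = p$medical_scoops,
                     grams = p$medical_scoops * p$scoop_grams),
      water_ml = p$water_ml,
      feeds = lapply(seq_len(nrow(p$per_feed)), function(i)
        list(commercial_scoops = p$per_feed$commercial_scoops[i],
             medical_scoops = p$per_feed$medical_scoops[i],
             water_ml = p$per_feed$water_ml[i]))),
    delivered = p$delivered,
    limiting_nutrient = p$limiting_nutrient,
    flags = as.list(p$flags),
    rdr_path = as.list(rec$rdr_path))
}

#' @export
print.msud_recommendation <- function(x, ...) {
  a <- x$allowance
  p <- x$plan
  cat("Recommended daily intake\n")
  cat(sprintf("  leucine    %8.1f mg\n", a$leucine_mg))
  cat(sprintf("  isoleucine %8.1f mg\n", a$isoleucine_mg))
  cat(sprintf("  valine     %8.1f mg\n", a$valine_mg))
  cat(sprintf("  protein    %8.2f g\n", a$protein_g))
  cat(sprintf("  energy     %8.1f kcal\n", a$energy_kcal))
  cat(sprintf("  fluid      %8.1f mL\n", a$fluid_ml))
  if (!is.null(a$adjustment_applied)) {
    cat("  adjustment:", a$adjustment_applied, "\n")
  }
  cat("\nFeeding plan (", p$scoop_grams, "g scoops, ", p$feeds_per_day,
      " feeds/day)\n", sep = "")
  cat(sprintf("  commercial %s: %d scoops (%.0f g)\n",
              x$formulas$commercial %||% "-", p$commercial_scoops,
              p$commercial_scoops * p$scoop_grams))
  cat(sprintf("  medical    %s: %d scoops (%.0f g)\n",
              x$formulas$medical %||% "-", p$medical_scoops,
              p$medical_scoops * p$scoop_grams))
  cat(sprintf("  water: %.0f mL/day\n", p$water_ml))
  cat(sprintf(
    "  delivered: leu %.1f mg, ile %.1f mg, val %.1f mg, protein %.2f g, energy %.1f kcal\n",
    p$delivered$leucine_mg, p$delivered$isoleucine_mg, p$delivered$valine_mg,
    p$delivered$protein_g, p$delivered$energy_kcal))
  if (p$limiting_nutrient != "none") {
    cat("  limiting nutrient:", p$limiting_nutrient, "\n")
  }
  if (length(p$flags)) cat("  flags:", paste(p$flags, collapse = ", "), "\n")
  invisible(x)
}
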