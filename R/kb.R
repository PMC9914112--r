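#' @title Nutrition knowledge base
#' @description
#' The verified knowledge the dosing engine runs on: a per-age table of daily
#' per-kg allowances (leucine, isoleucine, valine in mg/kg/day; protein in
#' g/kg/day; energy in kcal/kg/day; fluid in mL/kg/day) over six monthly age
#' bands, a composition table for six formulas (three commercial, three
#' medical, nutrients per 100 g of powder), and the runtime configuration
#' (scoop size, tolerances, feeds per day, plasma therapeutic bands).
#' Medical metabolic formulas contain no branched-chain amino acids, which is
#' what makes them the protein/energy filler of choice for MSUD.
#' @name knowledge_base
NULL

ALLOWANCE_COLS <- c("age_band", "isoleucine_mg_per_kg", "leucine_mg_per_kg",
                    "valine_mg_per_kg", "protein_g_per_kg",
                    "energy_kcal_per_kg", "fluid_ml_per_kg")
FORMULA_COLS <- c("name", "category", "leucine_mg_per_100g",
                  "isoleucine_mg_per_100g", "valine_mg_per_100g",
                  "protein_g_per_100g", "energy_kcal_per_100g")

kb_file <- function(name) {
  system.file("extdata", name, package = "msudbuddy", mustWork = TRUE)
}

# case-insensitive matching after trimming trademark glyphs and whitespace
normalize_name <- function(x) {
  tolower(trimws(gsub("[®™]", "", x)))
}

#' Load and validate the knowledge base
#'
#' With no arguments, loads the packaged tables and configuration. Every type
#' invariant is checked at load time; a violation aborts with the offending
#' row and field.
#'
#' @param allowance_source CSV path for the allowance table (default: packaged).
#' @param formula_source CSV path for the formula table (default: packaged).
#' @param config_source YAML path for the configuration (default: packaged).
#' @return a `msud_kb` list with elements `allowances` (data.frame),
#'   `formulas` (data.frame) and `config` (list).
#' @examples
#' kb <- load_kb()
#' nrow(kb$allowances)  # 6 monthly bands
#' @export
load_kb <- function(allowance_source = NULL, formula_source = NULL,
                    config_source = NULL) {
  allowance_source <- allowance_source %||% kb_file("allowances.csv")
  formula_source <- formula_source %||% kb_file("formulas.csv")
  config_source <- config_source %||% kb_file("config.yaml")

  allow <- utils::read.csv(allowance_source, stringsAsFactors = FALSE)
  if (!identical(names(allow), ALLOWANCE_COLS)) {
    stop("allowance table: expected columns ",
         paste(ALLOWANCE_COLS, collapse = ","), call. = FALSE)
  }
  for (b in 1:6) {
    hits <- sum(allow$age_band == b)
    if (hits == 0L) stop("allowance table: missing age band ", b, call. = FALSE)
    if (hits > 1L) stop("allowance table: duplicate age band ", b, call. = FALSE)
  }
  if (nrow(allow) != 6L) {
    stop("allowance table: age bands outside 1..6 present", call. = FALSE)
  }
  for (col in ALLOWANCE_COLS[-1]) {
    bad <- which(!is.finite(allow[[col]]) | allow[[col]] <= 0)
    if (length(bad)) {
      stop("allowance table row ", bad[1L], " (band ",
           allow$age_band[bad[1L]], "), field '", col,
           "': value must be strictly positive", call. = FALSE)
    }
  }
  allow <- allow[order(allow$age_band), , drop = FALSE]
  rownames(allow) <- NULL

  form <- utils::read.csv(formula_source, stringsAsFactors = FALSE)
  if (!identical(names(form), FORMULA_COLS)) {
    stop("formula table: expected columns ",
         paste(FORMULA_COLS, collapse = ","), call. = FALSE)
  }
  if (anyDuplicated(normalize_name(form$name))) {
    dup <- form$name[duplicated(normalize_name(form$name))][1L]
    stop("formula table: duplicate formula name '", dup, "'", call. = FALSE)
  }
  if (!all(form$category %in% c("commercial", "medical"))) {
    stop("formula table: category must be 'commercial' or 'medical'",
         call. = FALSE)
  }
  for (i in seq_len(nrow(form))) {
    if (form$category[i] == "medical") {
      for (col in c("leucine_mg_per_100g", "isoleucine_mg_per_100g",
                    "valine_mg_per_100g")) {
        if (form[[col]][i] != 0) {
          stop("formula table row ", i, " ('", form$name[i], "'), field '",
               col, "': a medical formula must be BCAA-free (value 0)",
               call. = FALSE)
        }
      }
    }
    for (col in c("protein_g_per_100g", "energy_kcal_per_100g")) {
      if (!is.finite(form[[col]][i]) || form[[col]][i] <= 0) {
        stop("formula table row ", i, " ('", form$name[i], "'), field '",
             col, "': value must be strictly positive", call. = FALSE)
      }
    }
  }

  config <- load_kb_config(config_source)
  structure(list(allowances = allow, formulas = form, config = config),
            class = "msud_kb")
}

load_kb_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(scoop_grams = 5, energy_tolerance = 0.10,
                   protein_tolerance = 0.10)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (!is.numeric(cfg$scoop_grams) || cfg$scoop_grams <= 0) {
    stop("config: scoop_grams must be > 0", call. = FALSE)
  }
  for (k in c("energy_tolerance", "protein_tolerance")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 0.5) {
      stop("config: ", k, " must lie in (0, 0.5)", call. = FALSE)
    }
  }
  fpd <- cfg$feeds_per_day_by_band
  if (is.null(fpd)) fpd <- as.list(stats::setNames(c(8, 8, 8, 6, 6, 6), 1:6))
  fpd <- lapply(fpd, as.integer)
  if (any(unlist(fpd) < 1L)) {
    stop("config: feeds_per_day must be >= 1", call. = FALSE)
  }
  cfg$feeds_per_day_by_band <- fpd
  if (is.null(cfg$plasma_bands)) {
    cfg$plasma_bands <- list(
      leucine = list(low_max = 75, high_min = 200),
      isoleucine = list(low_max = 200, high_min = 400),
      valine = list(low_max = 200, high_min = 400))
  }
  cfg
}

#' Look up the per-kg daily allowance for an age
#'
#' Ages are mapped to monthly bands by `ceiling(age_months)` clamped to
#' `[1, 6]`; age 0 (birth) maps to band 1. Fractional ages are accepted
#' because allowances are reassessed every few weeks in practice.
#'
#' @param kb a knowledge base from [load_kb()].
#' @param age_months age in months, in `[0, 6]`.
#' @return one-row data.frame: the `PerKgAllowance` record for the band.
#' @examples
#' kb <- load_kb()
#' lookup_allowance(kb, 3)$leucine_mg_per_kg  # 92.5
#' @export
lookup_allowance <- function(kb, age_months) {
  stopifnot(inherits(kb, "msud_kb"))
  if (!is.numeric(age_months) || length(age_months) != 1L ||
      !is.finite(age_months) || age_months < 0 || age_months > 6) {
    stop("age_months must be a number in [0, 6] months (ages beyond half a ",
         "year are outside the supported span)", call. = FALSE)
  }
  band <- min(6L, max(1L, as.integer(ceiling(age_months))))
  kb$allowances[kb$allowances$age_band == band, , drop = FALSE]
}

#' Look up a formula composition by name
#'
#' Matching is case-insensitive and ignores trademark glyphs and surrounding
#' whitespace, so `"similac"` and `"Similac®"` resolve identically.
#'
#' @param kb a knowledge base from [load_kb()].
#' @param name formula name.
#' @return one-row data.frame: the `FormulaComposition` record.
#' @export
lookup_formula <- function(kb, name) {
  stopifnot(inherits(kb, "msud_kb"), is.character(name), length(name) == 1L)
  hit <- which(normalize_name(kb$formulas$name) == normalize_name(name))
  if (length(hit) != 1L) {
    stop("unknown formula '", name, "'; available: ",
         paste(kb$formulas$name, collapse = ", "), call. = FALSE)
  }
  kb$formulas[hit, , drop = FALSE]
}

#' @export
print.msud_kb <- function(x, ...) {
  cat("MSUD nutrition knowledge base\n\nPer-kg daily allowances by age band:\n")
  print(x$allowances, row.names = FALSE)
  cat("\nFormula compositions (per 100 g powder):\n")
  print(x$formulas, row.names = FALSE)
  cat("\nScoop size:", x$config$scoop_grams, "g\n")
  invisible(x)
}
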