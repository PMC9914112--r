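#' @title Patient intake: profiles, plasma panels, formula selection
#' @description
#' Constructors and validators for the caregiver-supplied inputs. Validation
#' reports *every* offending field by name (not just the first), and an empty
#' formula selection is rejected with the literal message
#' "Please select formula".
#' @name patient_intake
NULL

#' Patient profile
#'
#' @param age_months age in months, in `[0, 6]` (the supported infant span).
#' @param weight_kg body weight in kg, in `(0, 15]`.
#' @param height_cm optional length in cm; recorded for the clinical record
#'   but not used by any dosing rule.
#' @return a `patient_profile` list.
#' @export
patient_profile <- function(age_months, weight_kg, height_cm = NULL) {
  if (!is.numeric(age_months) || length(age_months) != 1L ||
      !is.finite(age_months) || age_months < 0 || age_months > 6) {
    stop("profile: age_months must be in [0, 6] months", call. = FALSE)
  }
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L ||
      !is.finite(weight_kg) || weight_kg <= 0 || weight_kg > 15) {
    stop("profile: weight_kg must be in (0, 15] kg", call. = FALSE)
  }
  structure(list(age_months = age_months, weight_kg = weight_kg,
                 height_cm = height_cm), class = "patient_profile")
}

#' Plasma BCAA panel
#'
#' @param leucine,isoleucine,valine plasma concentrations in umol/L, or
#'   `NULL` when the field was left blank.
#' @return a `plasma_panel` list.
#' @export
plasma_panel <- function(leucine = NULL, isoleucine = NULL, valine = NULL) {
  structure(list(leucine = leucine, isoleucine = isoleucine, valine = valine),
            class = "plasma_panel")
}

#' Validate a plasma panel
#'
#' A panel passes when all three values are present, finite and nonnegative.
#' Otherwise validation fails with an error naming every invalid field, so
#' the caregiver can correct the whole form in one pass.
#'
#' @param panel a [plasma_panel()].
#' @return the panel, invisibly, on success.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "plasma_panel"))
  bad <- character(0)
  for (f in c("leucine", "isoleucine", "valine")) {
    v <- panel[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 0) {
      bad <- c(bad, f)
    }
  }
  if (length(bad)) {
    stop(validation_error(
      paste0("invalid plasma field(s): ", paste(bad, collapse = ", "),
             " (each must be a nonnegative number in umol/L)"),
      fields = bad))
  }
  invisible(panel)
}

validation_error <- function(message, fields = character(0)) {
  structure(class = c("msud_validation_error", "error", "condition"),
            list(message = message, call = NULL, fields = fields))
}

#' Formula selection
#'
#' @param commercial name of the chosen commercial formula, or `NULL`.
#' @param medical name of the chosen medical formula, or `NULL`.
#' @return a `formula_selection` list.
#' @export
formula_selection <- function(commercial = NULL, medical = NULL) {
  structure(list(commercial = commercial, medical = medical),
            class = "formula_selection")
}

#' Validate a formula selection against the knowledge base
#'
#' At least one formula must be chosen; an empty selection fails with the
#' literal message "Please select formula". Each named formula must exist in
#' the knowledge base and sit in the declared category slot (a medical
#' formula named in the commercial slot is a category mismatch, and vice
#' versa).
#'
#' @param selection a [formula_selection()].
#' @param kb a knowledge base from [load_kb()].
#' @return list with `commercial` and `medical` composition rows (either may
#'   be `NULL`), invisibly usable downstream.
#' @export
validate_selection <- function(selection, kb) {
  stopifnot(inherits(selection, "formula_selection"), inherits(kb, "msud_kb"))
  if (is.null(selection$commercial) && is.null(selection$medical)) {
    stop(validation_error("Please select formula"))
  }
  resolve <- function(name, slot) {
    if (is.null(name)) return(NULL)
    row <- lookup_formula(kb, name)
    if (row$category != slot) {
      stop(validation_error(paste0(
        "category mismatch: '", row$name, "' is a ", row$category,
        " formula but was selected in the ", slot, " slot")))
    }
    row
  }
  list(commercial = resolve(selection$commercial, "commercial"),
       medical = resolve(selection$medical, "medical"))
}

#' Flatten validated inputs into an RDR case
#'
#' Produces the flat attribute record the rule engine consumes. Absent fields
#' are omitted entirely (so `absent`-operator rules can see them), and height
#' is never included: no dosing rule reads it.
#'
#' @param profile a [patient_profile()].
#' @param panel a [plasma_panel()] (possibly partial).
#' @param selection a [formula_selection()] (possibly partial).
#' @return an [rdr_case()].
#' @export
to_case <- function(profile, panel = plasma_panel(),
                    selection = formula_selection()) {
  stopifnot(inherits(profile, "patient_profile"))
  rdr_case(list(
    age_months = profile$age_months,
    weight_kg = profile$weight_kg,
    plasma_leucine = panel$leucine,
    plasma_isoleucine = panel$isoleucine,
    plasma_valine = panel$valine,
    commercial_formula = selection$commercial,
    medical_formula = selection$medical))
}

#' Read a patient record from JSON
#'
#' Schema: `{"age_months": number, "weight_kg": number, "height_cm":
#' number|null, "plasma": {"leucine","isoleucine","valine"}, "formulas":
#' {"commercial": string|null, "medical": string|null}}`. `plasma` and
#' `formulas` may be omitted or partial; validation happens downstream.
#'
#' @param path path to a patient JSON file.
#' @return list with `profile`, `panel`, `selection`.
#' @export
read_patient_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("age_months", "weight_kg", "height_cm", "plasma", "formulas")
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    stop("patient file: unknown key '", extra[1L], "'", call. = FALSE)
  }
  profile <- patient_profile(as.numeric(doc$age_months),
                             as.numeric(doc$weight_kg),
                             if (!is.null(doc$height_cm))
                               as.numeric(doc$height_cm))
  pl <- doc$plasma %||% list()
  panel <- plasma_panel(leucine = pl$leucine, isoleucine = pl$isoleucine,
                        valine = pl$valine)
  fm <- doc$formulas %||% list()
  selection <- formula_selection(commercial = fm$commercial,
                                 medical = fm$medical)
  list(profile = profile, panel = panel, selection = selection)
}
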