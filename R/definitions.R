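# Case definitions: a cause label, an applicable-strata set, and a
# predicate tree. The AIDS and diarrhea screens follow the published study
# wording exactly; all other definitions are reconstructed from WHO-style
# verbal-autopsy indicators and ship as editable configuration.

#' Construct a case definition
#'
#' @param cause Cause label (string).
#' @param predicate A `va_predicate` tree (see [predicates]).
#' @param strata Strata the definition applies to: subset of
#'   `c("neonate", "child")`.
#' @param reconstructed Logical flag: `TRUE` marks a definition whose exact
#'   published wording was not available and which was reconstructed from
#'   standard VA indicators.
#' @return Object of class `case_definition`.
#' @export
case_definition <- function(cause, predicate, strata,
                            reconstructed = FALSE) {
  stopifnot(is.character(cause), length(cause) == 1L,
            inherits(predicate, "va_predicate"),
            all(strata %in% c("neonate", "child")), length(strata) >= 1L)
  structure(list(cause = cause, predicate = predicate,
                 strata = unique(strata),
                 reconstructed = isTRUE(reconstructed)),
            class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition> ", x$cause, " [",
      paste(x$strata, collapse = ", "), "]",
      if (x$reconstructed) " (reconstructed)", "\n", sep = "")
  invisible(x)
}

#' Evaluate a case definition on one record
#'
#' @param defn A [case_definition()].
#' @param record One-row slice of a [va_records()] table, or a named list of
#'   responses.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_definition <- function(defn, record) {
  stopifnot(inherits(defn, "case_definition"))
  eval_predicate(defn$predicate, record)
}

#' Tunable parameters of the built-in case definitions
#'
#' @param min_stools_per_day Minimum stools on the worst day for the
#'   diarrhea screen (default 6).
#' @param chronic_days_min First day counting as "more than 1 month"
#'   (default 31, i.e. strictly more than 30 days).
#' @param aids_resp_min_days,aids_resp_max_days Closed window, in days, of
#'   the respiratory AIDS condition ("cough or trouble breathing lasting 3
#'   to 27 days"; defaults 3 and 27).
#' @param diarrhea_symptom_only If `TRUE`, the diarrhea screen requires
#'   loose/liquid stools only, without the stool-count threshold — the
#'   symptom-prevalence variant used for data-quality probing.
#' @return Named list of parameters.
#' @export
va_parameters <- function(min_stools_per_day = 6,
                          chronic_days_min = 31,
                          aids_resp_min_days = 3,
                          aids_resp_max_days = 27,
                          diarrhea_symptom_only = FALSE) {
  list(min_stools_per_day = min_stools_per_day,
       chronic_days_min = chronic_days_min,
       aids_resp_min_days = aids_resp_min_days,
       aids_resp_max_days = aids_resp_max_days,
       diarrhea_symptom_only = isTRUE(diarrhea_symptom_only))
}

#' The built-in case-definition set
#'
#' Returns the default definitions for the two age strata. For neonates
#' (0--27 days): tetanus, congenital abnormalities, intrapartum-related
#' complications, preterm birth complications, pneumonia, diarrhea,
#' neonatal sepsis, other neonatal disorders. For children (1--59 months):
#' measles, injury, pneumonia (ARI), meningitis/encephalitis, malaria,
#' AIDS, diarrhea, other infections.
#'
#' The AIDS screen is the disjunction of five conditions: (1) jaundice;
#' (2) chronic diarrhea lasting more than 1 month; (3) chronic fever
#' lasting more than 1 month; (4) wasting, i.e. at least one of paleness,
#' hair colour change, edema of the legs, dry scaly skin; (5) cough or
#' trouble breathing lasting 3 to 27 days with fever and without a recent
#' tuberculosis diagnosis. The diarrhea screen requires loose/liquid
#' stools and at least `min_stools_per_day` stools on the day symptoms
#' were most severe. All other screens are reconstructions from WHO-style
#' VA indicators and carry `reconstructed = TRUE`.
#'
#' @param parameters See [va_parameters()].
#' @param codebook Codebook to validate the definitions against.
#' @return Named list of [case_definition()] objects (class
#'   `va_definitions`).
#' @export
builtin_definitions <- function(parameters = va_parameters(),
                                codebook = builtin_codebook()) {
  p <- parameters
  yes <- p_item_equals

  diarrhea_pred <- if (p$diarrhea_symptom_only) {
    yes("loose_stools")
  } else {
    p_all(yes("loose_stools"),
          p_item_at_least("stools_per_day", p$min_stools_per_day))
  }

  aids_resp <- p_all(
    p_any(p_all(yes("cough"),
                p_duration("cough_duration_days",
                           p$aids_resp_min_days, p$aids_resp_max_days)),
          p_all(yes("trouble_breathing"),
                p_duration("breathing_duration_days",
                           p$aids_resp_min_days, p$aids_resp_max_days))),
    yes("fever"),
    p_none(yes("tb_diagnosis_recent"))
  )

  defs <- list(
    # ---- neonatal (0-27 d) ----
    case_definition("tetanus",
      p_all(yes("suckled_normally_first_2d"), yes("stopped_suckling"),
            yes("spasms")),
      "neonate", reconstructed = TRUE),
    case_definition("congenital",
      p_all(yes("malformation"),
            p_any(yes("malformation_head"), yes("malformation_spine"),
                  yes("malformation_limb"), yes("malformation_other"))),
      "neonate", reconstructed = TRUE),
    case_definition("intrapartum",
      p_any(yes("not_cry_after_birth"), yes("not_breathe_after_birth")),
      "neonate", reconstructed = TRUE),
    case_definition("preterm",
      p_any(yes("born_early"), yes("very_small_at_birth")),
      "neonate", reconstructed = TRUE),
    case_definition("pneumonia",
      p_all(p_any(yes("cough"), yes("trouble_breathing")),
            p_any(yes("fast_breathing"), yes("chest_indrawing"))),
      c("neonate", "child"), reconstructed = TRUE),
    case_definition("diarrhea", diarrhea_pred, c("neonate", "child")),
    case_definition("sepsis",
      p_all(p_any(yes("fever"), yes("cold_to_touch")),
            p_any(yes("stopped_suckling"), yes("lethargic"))),
      "neonate", reconstructed = TRUE),
    case_definition("other_neonatal",
      p_any(yes("convulsions"), yes("jaundice")),
      "neonate", reconstructed = TRUE),
    # ---- child (1-59 m) ----
    case_definition("measles",
      p_all(yes("rash"), yes("fever"),
            p_any(yes("rash_on_face"),
                  p_duration("rash_duration_days", 3, Inf))),
      "child", reconstructed = TRUE),
    case_definition("injury",
      p_all(yes("injury_accident"),
            p_any(yes("road_accident"), yes("fall"), yes("drowning"),
                  yes("burn"), yes("poisoning"), yes("animal_bite"))),
      "child", reconstructed = TRUE),
    case_definition("meningitis",
      p_all(yes("fever"),
            p_any(yes("stiff_neck"), yes("bulging_fontanelle"))),
      "child", reconstructed = TRUE),
    case_definition("malaria",
      p_all(yes("fever"),
            p_any(yes("convulsions"), yes("unconscious"))),
      "child", reconstructed = TRUE),
    case_definition("aids",
      p_any(
        yes("jaundice"),
        p_all(yes("loose_stools"),
              p_duration("diarrhea_duration_days", p$chronic_days_min, Inf)),
        p_all(yes("fever"),
              p_duration("fever_duration_days", p$chronic_days_min, Inf)),
        p_any(yes("paleness"), yes("hair_color_change"),
              yes("edema_legs"), yes("dry_scaly_skin")),
        aids_resp
      ),
      "child"),
    case_definition("other_infections",
      yes("fever"),
      "child", reconstructed = TRUE)
  )
  defs <- setNames(defs, vapply(defs, `[[`, "", "cause"))
  for (d in defs) {
    validate_predicate(d$predicate, codebook, paste0("definition '",
                                                     d$cause, "'"))
  }
  attr(defs, "parameters") <- p
  class(defs) <- "va_definitions"
  defs
}

#' Causes with a definition applicable in a stratum
#' @param defs A `va_definitions` list.
#' @param stratum `"neonate"` or `"child"`.
#' @return Character vector of cause labels.
#' @export
causes_for_stratum <- function(defs, stratum) {
  names(defs)[vapply(defs, function(d) stratum %in% d$strata, TRUE)]
}

definitions_to_list <- function(defs) {
  list(definitions = lapply(unname(defs), function(d) {
    list(cause = d$cause,
         strata = as.list(d$strata),
         reconstructed = d$reconstructed,
         predicate = predicate_to_list(d$predicate))
  }))
}

#' Write case definitions to YAML
#' @param defs A `va_definitions` list.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_definitions <- function(defs, path) {
  yaml::write_yaml(definitions_to_list(defs), path)
  invisible(path)
}

#' Load case definitions from a YAML/JSON config
#'
#' The config may carry a `parameters` map (overriding [va_parameters()]
#' defaults used to build the base set) and/or a `definitions` array whose
#' entries replace the base definition for their cause label. A cause label
#' absent from the base set is rejected unless `allow_new_causes = TRUE`.
#' Every predicate leaf is checked against the codebook at load time —
#' never at evaluation time. An empty config reproduces
#' [builtin_definitions()] exactly. A JSON Schema for the format ships
#' under `system.file("schema", "definitions.schema.json",
#' package = "vacause")`.
#'
#' @param path Path to `.yaml`/`.yml`/`.json` config.
#' @param codebook A [va_codebook()].
#' @param allow_new_causes Permit cause labels not in the built-in set.
#' @return A `va_definitions` list.
#' @export
load_definitions <- function(path, codebook = builtin_codebook(),
                             allow_new_causes = FALSE) {
  cfg <- read_config(path)
  if (!is.list(cfg)) stop(path, ": config must be a map", call. = FALSE)
  unknown_keys <- setdiff(names(cfg), c("parameters", "definitions"))
  if (length(unknown_keys)) {
    stop(path, ": unknown top-level key(s): ",
         paste(unknown_keys, collapse = ", "), call. = FALSE)
  }
  params <- do.call(va_parameters, cfg$parameters %||% list())
  defs <- builtin_definitions(params, codebook)

  for (i in seq_along(cfg$definitions)) {
    entry <- cfg$definitions[[i]]
    where <- paste0(path, ": definitions[", i, "]")
    if (is.null(entry$cause) || is.null(entry$predicate)) {
      stop(where, " lacks 'cause' or 'predicate'", call. = FALSE)
    }
    if (!entry$cause %in% names(defs) && !allow_new_causes) {
      stop(where, ": unknown cause label '", entry$cause, "'",
           call. = FALSE)
    }
    pred <- predicate_from_list(entry$predicate, where)
    validate_predicate(pred, codebook, where)
    strata <- unlist(entry$strata) %||% defs[[entry$cause]]$strata
    defs[[entry$cause]] <- case_definition(
      entry$cause, pred, strata,
      reconstructed = isTRUE(entry$reconstructed)
    )
  }
  attr(defs, "parameters") <- params
  class(defs) <- "va_definitions"
  defs
}
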