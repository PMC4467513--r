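# Age-stratified cause hierarchies and the assignment walk.
#
# Causes are evaluated in a fixed order, more specific diagnoses first.
# The first true definition outside the multi-cause group wins and stops
# the walk. Members of the multi-cause group (measles, diarrhea and ARI in
# the child stratum) do not stop the walk for each other: once any group
# member fires, only the remaining group members are still evaluated and
# every true one is recorded, producing a provisional multi-cause set that
# is later resolved by redistribution. A record matching nothing is
# "unspecified".

UNSPECIFIED <- "unspecified"

#' Construct a cause hierarchy for one age stratum
#'
#' @param stratum `"neonate"` or `"child"`.
#' @param ordered_causes Cause labels in evaluation order.
#' @param multi_cause_group Subset of `ordered_causes` assigned jointly
#'   rather than first-hit (empty in the neonatal stratum).
#' @param fallback_cause Label for deaths matching no definition.
#' @return Object of class `va_hierarchy`.
#' @export
va_hierarchy <- function(stratum, ordered_causes,
                         multi_cause_group = character(),
                         fallback_cause = UNSPECIFIED) {
  stopifnot(stratum %in% c("neonate", "child"),
            is.character(ordered_causes), length(ordered_causes) >= 1L)
  if (anyDuplicated(ordered_causes)) {
    stop("ordered_causes contains duplicates", call. = FALSE)
  }
  if (!all(multi_cause_group %in% ordered_causes)) {
    stop("multi_cause_group must be a subset of ordered_causes",
         call. = FALSE)
  }
  structure(list(stratum = stratum,
                 ordered_causes = ordered_causes,
                 multi_cause_group = multi_cause_group,
                 fallback_cause = fallback_cause),
            class = "va_hierarchy")
}

#' @export
print.va_hierarchy <- function(x, ...) {
  marked <- ifelse(x$ordered_causes %in% x$multi_cause_group,
                   paste0(x$ordered_causes, "*"), x$ordered_causes)
  cat("<va_hierarchy> ", x$stratum, ": ",
      paste(marked, collapse = " > "), " > ", x$fallback_cause,
      if (length(x$multi_cause_group)) "   (* joint multi-cause group)",
      "\n", sep = "")
  invisible(x)
}

#' Default hierarchies for the two age strata
#'
#' The child hierarchy enforces the published placement constraints:
#' pneumonia/ARI before meningitis/encephalitis, meningitis before
#' malaria, malaria before AIDS; measles, diarrhea and pneumonia form the
#' multi-cause group. The neonatal hierarchy contains neither malaria nor
#' AIDS (both were deliberately not assigned among neonates) and places
#' sepsis after pneumonia and diarrhea. The full order beyond those
#' constraints follows the more-specific-before-less-specific principle
#' and is a reconstruction, shipped as editable configuration.
#'
#' @return Named list (`neonate`, `child`) of [va_hierarchy()] objects.
#' @export
default_hierarchies <- function() {
  list(
    neonate = va_hierarchy(
      "neonate",
      c("tetanus", "congenital", "intrapartum", "preterm",
        "pneumonia", "diarrhea", "sepsis", "other_neonatal")
    ),
    child = va_hierarchy(
      "child",
      c("measles", "injury", "pneumonia", "meningitis", "malaria",
        "aids", "diarrhea", "other_infections"),
      multi_cause_group = c("measles", "diarrhea", "pneumonia")
    )
  )
}

#' Validate a hierarchy against its definitions and placement constraints
#'
#' Checks that every ordered cause has a definition applicable to the
#' stratum, and (unless `allow_order_override = TRUE`) that the published
#' placement constraints hold: in the child stratum
#' pneumonia < meningitis < malaria < aids (where present); the neonatal
#' stratum must not contain malaria or aids, and sepsis must come after
#' pneumonia and diarrhea (where present).
#'
#' @param hierarchy A [va_hierarchy()].
#' @param defs A `va_definitions` list.
#' @param allow_order_override Skip the placement-constraint checks.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_hierarchy <- function(hierarchy, defs,
                               allow_order_override = FALSE) {
  stopifnot(inherits(hierarchy, "va_hierarchy"))
  check_coverage <- function() {
    available <- causes_for_stratum(defs, hierarchy$stratum)
    missing <- setdiff(hierarchy$ordered_causes, available)
    if (length(missing)) {
      stop("cause(s) in hierarchy without a ", hierarchy$stratum,
           " definition: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (allow_order_override) {
    check_coverage()
    return(invisible(TRUE))
  }
  idx <- function(cause) match(cause, hierarchy$ordered_causes)
  before <- function(a, b) {
    # constraint applies only when both causes are present
    is.na(idx(a)) || is.na(idx(b)) || idx(a) < idx(b)
  }
  if (hierarchy$stratum == "child") {
    if (!(before("pneumonia", "meningitis") &&
            before("meningitis", "malaria") && before("malaria", "aids"))) {
      stop("child hierarchy violates the placement constraints ",
           "pneumonia < meningitis < malaria < aids ",
           "(use allow_order_override to force)", call. = FALSE)
    }
  } else {
    banned <- intersect(c("malaria", "aids"), hierarchy$ordered_causes)
    if (length(banned)) {
      stop("neonatal hierarchy must not assign: ",
           paste(banned, collapse = ", "),
           " (use allow_order_override to force)", call. = FALSE)
    }
    if (!(before("pneumonia", "sepsis") && before("diarrhea", "sepsis"))) {
      stop("neonatal hierarchy must place sepsis after pneumonia and ",
           "diarrhea (use allow_order_override to force)", call. = FALSE)
    }
  }
  check_coverage()
  invisible(TRUE)
}

#' Load hierarchies from a YAML/JSON config
#'
#' Expected shape: a map with `neonate`/`child` entries, each carrying
#' `ordered_causes` (list) and optionally `multi_cause_group` and
#' `fallback_cause`. The placement constraints of
#' [validate_hierarchy()] are enforced unless the config sets
#' `allow_order_override: true`.
#'
#' @param path Config path.
#' @param defs Definitions to validate against.
#' @return Named list of [va_hierarchy()] objects.
#' @export
load_hierarchies <- function(path, defs = builtin_definitions()) {
  cfg <- read_config(path)
  override <- isTRUE(cfg$allow_order_override)
  strata <- intersect(c("neonate", "child"), names(cfg))
  if (!length(strata)) {
    stop(path, ": no 'neonate' or 'child' hierarchy found", call. = FALSE)
  }
  out <- lapply(strata, function(s) {
    entry <- cfg[[s]]
    h <- va_hierarchy(s, unlist(entry$ordered_causes),
                      multi_cause_group = unlist(entry$multi_cause_group) %||%
                        character(),
                      fallback_cause = entry$fallback_cause %||% UNSPECIFIED)
    validate_hierarchy(h, defs, allow_order_override = override)
    h
  })
  setNames(out, strata)
}

#' Write hierarchies to YAML
#' @param hierarchies Named list of [va_hierarchy()] objects.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_hierarchies <- function(hierarchies, path) {
  yaml::write_yaml(lapply(hierarchies, function(h) {
    list(ordered_causes = as.list(h$ordered_causes),
         multi_cause_group = as.list(h$multi_cause_group),
         fallback_cause = h$fallback_cause)
  }), path)
  invisible(path)
}

# Core walk for one record. `responses` is a named list; returns
# list(provisional = character vector, trace = named logical vector of the
# evaluations actually performed, in order).
walk_hierarchy <- function(responses, hierarchy, defs) {
  group <- hierarchy$multi_cause_group
  fired_group <- character()
  trace <- logical()
  for (cause in hierarchy$ordered_causes) {
    in_group <- cause %in% group
    if (!in_group && length(fired_group)) next  # group already owns the walk
    res <- eval_predicate(defs[[cause]]$predicate, responses)
    trace[[cause]] <- res
    if (res) {
      if (in_group) {
        fired_group <- c(fired_group, cause)
      } else {
        return(list(provisional = cause, trace = trace))
      }
    }
  }
  if (length(fired_group)) {
    list(provisional = fired_group, trace = trace)
  } else {
    list(provisional = hierarchy$fallback_cause, trace = trace)
  }
}

#' Assign causes to included VA records
#'
#' Walks the stratum's ordered hierarchy for every record. Records whose
#' provisional set contains more than one cause (all members of the
#' multi-cause group) are left pending (`final_cause` is `NA`) until
#' [va_redistribute()] resolves them.
#'
#' @param records Included [va_records()] (see
#'   [apply_inclusion_criteria()]).
#' @param hierarchies Named list of hierarchies as from
#'   [default_hierarchies()].
#' @param defs A `va_definitions` list.
#' @param trace Keep the per-record rule trace (named logical list-column)?
#' @return A `va_assignments` data.frame: `record_id`, `stratum`,
#'   `provisional` (list-column of character vectors), `final_cause`
#'   (`NA` while pending), `pending`, and optionally `rule_trace`.
#' @export
va_assign <- function(records, hierarchies = default_hierarchies(),
                      defs = builtin_definitions(), trace = FALSE) {
  stopifnot(inherits(records, "va_records"))
  for (h in hierarchies) validate_hierarchy(h, defs)
  strata <- stratify(records$age_at_death_days)
  n <- nrow(records)
  provisional <- vector("list", n)
  traces <- if (trace) vector("list", n)
  df <- as.data.frame(records)
  item_cols <- intersect(codebook_ids(records_codebook(records)), names(df))
  cols <- as.list(df[item_cols])  # column-wise access: fast per-row slices
  for (i in seq_len(n)) {
    h <- hierarchies[[strata[i]]]
    if (is.null(h)) {
      stop("no hierarchy for stratum '", strata[i], "'", call. = FALSE)
    }
    w <- walk_hierarchy(lapply(cols, `[[`, i), h, defs)
    provisional[[i]] <- w$provisional
    if (trace) traces[[i]] <- w$trace
  }
  pending <- lengths(provisional) > 1L
  out <- data.frame(record_id = records$record_id,
                    stratum = strata,
                    final_cause = ifelse(pending, NA_character_,
                                         vapply(provisional, `[`, "", 1L)),
                    pending = pending,
                    stringsAsFactors = FALSE)
  out$provisional <- provisional
  if (trace) out$rule_trace <- traces
  class(out) <- c("va_assignments", "data.frame")
  out
}

#' Resolve multi-cause assignments by CSMF-proportional redistribution
#'
#' First computes, per stratum, the survey-weighted CSMFs of the
#' multi-cause group members using only records provisionally assigned to
#' exactly one of them. Each pending record is then resolved over its
#' provisional set in proportion to those pre-redistribution CSMFs. In
#' `"fractional"` mode (the default, fully deterministic) the record's
#' weight is split across its provisional causes; in `"sample"` mode one
#' cause is drawn per record with the same probabilities, reproducibly
#' from `seed`. If all relevant pre-redistribution CSMFs are zero the
#' split is equal (with a message).
#'
#' @param assignments A `va_assignments` table from [va_assign()].
#' @param records The matching [va_records()] (provides survey weights).
#' @param mode `"fractional"` or `"sample"`.
#' @param seed Integer seed (required for `"sample"` mode).
#' @return A `va_allocation` object: list with `assignments` (pending
#'   resolved; in fractional mode multi-cause records keep
#'   `final_cause = NA` but are no longer pending) and `allocations`, a
#'   long data.frame (`record_id`, `stratum`, `cause`, `fraction`,
#'   `weight`) in which every record's fractions sum to 1.
#' @export
va_redistribute <- function(assignments, records,
                            mode = c("fractional", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(assignments, "va_assignments"))
  w <- setNames(records$survey_weight, records$record_id)
  if (anyNA(w[assignments$record_id])) {
    stop("missing survey weight for some assigned records", call. = FALSE)
  }
  asg <- assignments
  asg$weight <- unname(w[asg$record_id])

  # pre-redistribution CSMFs of group members, per stratum, single-cause
  # records only
  group_csmf <- function(stratum, members) {
    sub <- asg[!asg$pending & asg$stratum == stratum &
                 asg$final_cause %in% members, , drop = FALSE]
    tot <- sum(asg$weight[asg$stratum == stratum])
    f <- vapply(members, function(cz) {
      sum(sub$weight[sub$final_cause == cz]) / tot
    }, 0)
    f
  }

  rows <- vector("list", nrow(asg))
  if (mode == "sample") {
    if (is.null(seed)) stop("sample mode requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
  }
  csmf_cache <- list()
  for (i in seq_len(nrow(asg))) {
    prov <- asg$provisional[[i]]
    if (!asg$pending[i]) {
      rows[[i]] <- data.frame(record_id = asg$record_id[i],
                              stratum = asg$stratum[i],
                              cause = asg$final_cause[i], fraction = 1,
                              weight = asg$weight[i],
                              stringsAsFactors = FALSE)
      next
    }
    key <- paste(asg$stratum[i], paste(sort(prov), collapse = "|"))
    if (is.null(csmf_cache[[key]])) {
      csmf_cache[[key]] <- group_csmf(asg$stratum[i], prov)
    }
    f <- csmf_cache[[key]]
    if (sum(f) <= 0) {
      message("all pre-redistribution CSMFs zero for {",
              paste(prov, collapse = ", "), "}; splitting equally")
      f <- rep(1, length(prov))
    }
    pr <- f / sum(f)
    if (mode == "fractional") {
      rows[[i]] <- data.frame(record_id = asg$record_id[i],
                              stratum = asg$stratum[i],
                              cause = prov, fraction = unname(pr),
                              weight = asg$weight[i],
                              stringsAsFactors = FALSE)
    } else {
      pick <- sample(prov, 1L, prob = pr)
      asg$final_cause[i] <- pick
      rows[[i]] <- data.frame(record_id = asg$record_id[i],
                              stratum = asg$stratum[i],
                              cause = pick, fraction = 1,
                              weight = asg$weight[i],
                              stringsAsFactors = FALSE)
    }
  }
  asg$pending <- FALSE
  alloc <- do.call(rbind, rows)
  rownames(alloc) <- NULL
  structure(list(assignments = asg, allocations = alloc, mode = mode),
            class = "va_allocation")
}

#' @export
print.va_allocation <- function(x, ...) {
  multi <- sum(x$allocations$fraction < 1)
  cat("<va_allocation> ", length(unique(x$allocations$record_id)),
      " records, mode = ", x$mode,
      if (multi) paste0(" (", multi, " fractional rows)"), "\n", sep = "")
  invisible(x)
}

#' Write assignments (and rule traces) to disk
#'
#' @param assignments A `va_assignments` table.
#' @param path Output CSV path (`record_id`, `stratum`, `final_cause`,
#'   `provisional_causes` semicolon-joined, `pending`).
#' @param trace_path Optional JSON-lines path; one object per record with
#'   the ordered evaluations performed (requires `va_assign(trace = TRUE)`).
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, trace_path = NULL) {
  df <- data.frame(
    record_id = assignments$record_id,
    stratum = assignments$stratum,
    final_cause = assignments$final_cause,
    provisional_causes = vapply(assignments$provisional, paste,
                                "", collapse = ";"),
    pending = assignments$pending,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(trace_path)) {
    if (is.null(assignments$rule_trace)) {
      stop("no rule traces stored; rerun va_assign(trace = TRUE)",
           call. = FALSE)
    }
    lines <- vapply(seq_len(nrow(assignments)), function(i) {
      tr <- assignments$rule_trace[[i]]
      jsonlite::toJSON(list(record_id = assignments$record_id[i],
                            evaluations = lapply(seq_along(tr), function(j) {
                              list(cause = names(tr)[j],
                                   result = unname(tr[j]))
                            })),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, trace_path)
  }
  invisible(path)
}
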