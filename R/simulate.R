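# Truth-known synthetic VA data.
#
# The generator is definition-aware: for each record it draws an age
# stratum and a true cause from the scenario CSMF, then emits a symptom
# profile that is a minimal satisfying assignment of the true cause's
# predicate tree, pre-screened so that the profile fires no definition
# placed above the true cause — at sensitivity 1 and false-positive rate
# 0 the hierarchy therefore recovers the truth exactly. A sensitivity
# miss emits an empty profile. False positives flip additional binary
# items to "yes" at the per-item rate, subject to the same emission
# contract: a flip that would make the profile satisfy a definition
# placed above the true cause's hierarchy position is rejected (duration
# and count items are never flipped, so threshold conditions cannot fire
# spuriously either). Noise therefore perturbs the record downward in the
# hierarchy — towards less specific diagnoses and "unspecified" — which
# mirrors under-reporting of signs; it never invents a more specific
# syndrome wholesale. A comparator coder is simulated from a per-stratum
# error matrix.

#' Minimal satisfying assignments of a predicate tree
#'
#' Enumerates the minimal response assignments (named lists item -> value)
#' under which the predicate evaluates true with all other items missing.
#' `all_of` crosses its children's assignments (conflicting values drop
#' the combination), `any_of` unions them, `none_of` is satisfied by the
#' empty assignment (missing-as-absent). Candidates are verified against
#' the full tree and non-minimal ones (supersets of another candidate)
#' are dropped.
#'
#' @param predicate A `va_predicate`.
#' @return List of named lists; empty if the predicate is unsatisfiable by
#'   assignment alone.
#' @export
minimal_assignments <- function(predicate) {
  gen <- function(p) {
    switch(p$kind,
      item_equals = list(setNames(list(p$value), p$item)),
      item_at_least = list(setNames(list(p$min_count), p$item)),
      duration_in_days = list(setNames(list(p$min_days), p$item)),
      any_of = unique(unlist(lapply(p$children, gen), recursive = FALSE)),
      none_of = list(list()),  # satisfied by absence
      all_of = {
        acc <- list(list())
        for (ch in p$children) {
          opts <- gen(ch)
          nxt <- list()
          for (a in acc) {
            for (b in opts) {
              shared <- intersect(names(a), names(b))
              if (all(vapply(shared, function(s) {
                identical(a[[s]], b[[s]])
              }, TRUE))) {
                nxt[[length(nxt) + 1L]] <- c(a, b[setdiff(names(b), shared)])
              }
            }
          }
          acc <- nxt
        }
        unique(acc)
      },
      stop("unknown predicate kind: ", p$kind, call. = FALSE)
    )
  }
  cand <- gen(predicate)
  cand <- Filter(function(a) eval_predicate(predicate, a), cand)
  # drop supersets of another satisfying assignment
  is_superset <- function(a, b) {
    length(b) < length(a) && all(names(b) %in% names(a)) &&
      all(vapply(names(b), function(s) identical(a[[s]], b[[s]]), TRUE))
  }
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      i != j && is_superset(cand[[i]], cand[[j]])
    }, TRUE))
  }, TRUE)
  unique(cand[keep])
}

# For each stratum and cause, the minimal assignments under which the full
# hierarchy walk recovers exactly that cause. Errors when a cause has no
# safe assignment (the hierarchy would mask it).
safe_profiles <- function(defs, hierarchies) {
  lapply(hierarchies, function(h) {
    out <- lapply(h$ordered_causes, function(cause) {
      cand <- minimal_assignments(defs[[cause]]$predicate)
      safe <- Filter(function(a) {
        w <- walk_hierarchy(a, h, defs)
        identical(w$provisional, cause)
      }, cand)
      if (!length(safe)) {
        stop("cause '", cause, "' (", h$stratum, ") has no satisfying ",
             "assignment that survives the hierarchy; it would never be ",
             "recovered", call. = FALSE)
      }
      safe
    })
    setNames(out, h$ordered_causes)
  })
}

check_csmf_vector <- function(x, stratum, causes) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("csmf_", stratum, " must be a named vector", call. = FALSE)
  }
  if (any(x < 0)) stop("negative CSMF in csmf_", stratum, call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8) {
    stop("csmf_", stratum, " must sum to 1 (got ", sum(x), ")",
         call. = FALSE)
  }
  bad <- setdiff(names(x), c(causes, UNSPECIFIED))
  if (length(bad)) {
    stop("csmf_", stratum, " names cause(s) without a case definition: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Define a simulation scenario
#'
#' @param n Total number of deaths.
#' @param p_neonatal Proportion of deaths in the neonatal stratum.
#' @param csmf_neonate,csmf_child Named true CSMF per stratum (may include
#'   `"unspecified"`, simulated as a profile satisfying no definition);
#'   each must sum to 1 and name only causes with a definition.
#' @param sensitivity Probability that a death's profile satisfies its
#'   true-cause definition (scalar, default 0.9).
#' @param fp_rate Per-item false-positive rate for binary items not in the
#'   emitted profile (default 0.02). Flips obey the emission contract: a
#'   flip that would make the profile satisfy a definition placed above
#'   the true cause's hierarchy position is rejected, so noise pushes
#'   records down the hierarchy, never up.
#' @param comparator_accuracy Probability the simulated comparator coder
#'   reproduces the true cause; the remainder is spread over the other
#'   causes of the stratum in proportion to the true CSMF (default 0.6,
#'   reflecting the fair-to-moderate agreement typical of VA coders).
#'   Ignored when explicit matrices are given.
#' @param comparator_matrix Optional named list (`neonate`, `child`) of
#'   row-stochastic matrices, rows/cols the stratum's causes plus
#'   `"unspecified"`: `P(comparator = j | truth = i)`.
#' @param n_strata,psus_per_stratum Survey design size (default 6 strata
#'   of 4 PSUs).
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param seed Integer seed; every draw in [simulate_va()] flows from it.
#' @param defs,hierarchies Definition set and hierarchies the scenario is
#'   simulated (and validated) against.
#' @return Object of class `va_scenario`.
#' @export
simulation_scenario <- function(n, p_neonatal, csmf_neonate, csmf_child,
                                sensitivity = 0.9, fp_rate = 0.02,
                                comparator_accuracy = 0.6,
                                comparator_matrix = NULL,
                                n_strata = 6, psus_per_stratum = 4,
                                weight_meanlog = 0, weight_sdlog = 0.5,
                                seed = 1L,
                                defs = builtin_definitions(),
                                hierarchies = default_hierarchies()) {
  stopifnot(n >= 0, p_neonatal >= 0, p_neonatal <= 1,
            sensitivity >= 0, sensitivity <= 1,
            fp_rate >= 0, fp_rate <= 1,
            comparator_accuracy >= 0, comparator_accuracy <= 1)
  csmf_neonate <- check_csmf_vector(csmf_neonate, "neonate",
                                    causes_for_stratum(defs, "neonate"))
  csmf_child <- check_csmf_vector(csmf_child, "child",
                                  causes_for_stratum(defs, "child"))
  if (!is.null(comparator_matrix)) {
    for (s in names(comparator_matrix)) {
      m <- comparator_matrix[[s]]
      if (any(abs(rowSums(m) - 1) > 1e-8) || any(m < 0)) {
        stop("comparator matrix for ", s, " is not row-stochastic",
             call. = FALSE)
      }
    }
  }
  structure(list(n = as.integer(n), p_neonatal = p_neonatal,
                 csmf = list(neonate = csmf_neonate, child = csmf_child),
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 comparator_accuracy = comparator_accuracy,
                 comparator_matrix = comparator_matrix,
                 n_strata = as.integer(n_strata),
                 psus_per_stratum = as.integer(psus_per_stratum),
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 seed = as.integer(seed),
                 defs = defs, hierarchies = hierarchies),
            class = "va_scenario")
}

#' @export
print.va_scenario <- function(x, ...) {
  cat("<va_scenario> n = ", x$n, " (", round(100 * x$p_neonatal, 1),
      "% neonatal), sensitivity ", x$sensitivity, ", fp ", x$fp_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Row-stochastic comparator matrix for one stratum from the scalar
# accuracy: diagonal = accuracy, remainder proportional to the CSMF of
# the other causes (uniform fallback when those are all zero).
build_comparator_matrix <- function(csmf, accuracy) {
  causes <- union(names(csmf), UNSPECIFIED)
  p <- setNames(rep(0, length(causes)), causes)
  p[names(csmf)] <- csmf
  m <- matrix(0, length(causes), length(causes),
              dimnames = list(causes, causes))
  for (i in causes) {
    others <- setdiff(causes, i)
    rest <- p[others]
    rest <- if (sum(rest) > 0) rest / sum(rest) else
      rep(1 / length(others), length(others))
    m[i, others] <- (1 - accuracy) * rest
    m[i, i] <- accuracy
  }
  m
}

#' Simulate a VA study with known truth
#'
#' Fully reproducible from the scenario seed: a single RNG stream drives,
#' per record and in a fixed documented order, the stratum draw, true
#' cause, age, survey design fields, weight, sensitivity coin, choice of
#' satisfying assignment, per-item false-positive coins, and the
#' comparator draw. (Because the stream is shared, changing `n` perturbs
#' all subsequent draws; scenarios are compared at equal `n`.)
#'
#' @param scenario A [simulation_scenario()].
#' @param codebook Codebook for the emitted records.
#' @return List with `records` (a [va_records()] table, all passing the
#'   inclusion criteria) and `truth` (data.frame `record_id`, `stratum`,
#'   `true_cause`, `weight`).
#' @export
simulate_va <- function(scenario, codebook = builtin_codebook()) {
  stopifnot(inherits(scenario, "va_scenario"))
  defs <- scenario$defs
  hierarchies <- scenario$hierarchies
  profiles <- safe_profiles(defs, hierarchies)
  n <- scenario$n

  kinds <- vapply(codebook, `[[`, "", "kind")
  bin_items <- names(kinds)[kinds == "binary"]
  num_items <- names(kinds)[kinds %in% c("count", "duration_days")]

  cmp_matrix <- scenario$comparator_matrix %||% list(
    neonate = build_comparator_matrix(scenario$csmf$neonate,
                                      scenario$comparator_accuracy),
    child = build_comparator_matrix(scenario$csmf$child,
                                    scenario$comparator_accuracy)
  )

  set.seed(scenario$seed)
  rec_id <- sprintf("r%05d", seq_len(n))
  stratum <- character(n)
  true_cause <- character(n)
  age <- integer(n)
  weight <- numeric(n)
  des_stratum <- character(n)
  des_psu <- character(n)
  comparator <- character(n)
  bin_mat <- matrix(NA_character_, n, length(bin_items),
                    dimnames = list(NULL, bin_items))
  num_mat <- matrix(NA_real_, n, length(num_items),
                    dimnames = list(NULL, num_items))

  for (i in seq_len(n)) {
    s <- if (runif(1) < scenario$p_neonatal) "neonate" else "child"
    stratum[i] <- s
    csmf <- scenario$csmf[[s]]
    tc <- sample(names(csmf), 1L, prob = csmf)
    true_cause[i] <- tc
    age[i] <- if (s == "neonate") sample(0:27, 1L) else sample(28:1826, 1L)
    ds <- sample.int(scenario$n_strata, 1L)
    des_stratum[i] <- sprintf("S%02d", ds)
    des_psu[i] <- sprintf("S%02d_P%02d", ds,
                          sample.int(scenario$psus_per_stratum, 1L))
    weight[i] <- rlnorm(1, scenario$weight_meanlog, scenario$weight_sdlog)

    resp <- list()
    if (tc != UNSPECIFIED && runif(1) < scenario$sensitivity) {
      opts <- profiles[[s]][[tc]]
      resp <- opts[[sample.int(length(opts), 1L)]]
    }
    if (scenario$fp_rate > 0) {
      ord <- hierarchies[[s]]$ordered_causes
      pos <- match(tc, ord)
      above <- if (is.na(pos)) ord else ord[seq_len(pos - 1L)]
      free <- setdiff(bin_items, names(resp))
      flips <- free[runif(length(free)) < scenario$fp_rate]
      for (it in flips) {
        trial <- resp
        trial[[it]] <- "yes"
        masked <- any(vapply(above, function(cz) {
          eval_predicate(defs[[cz]]$predicate, trial)
        }, TRUE))
        if (!masked) resp <- trial   # emission contract: never fire above
      }
    }
    for (nm in names(resp)) {
      if (nm %in% bin_items) bin_mat[i, nm] <- as.character(resp[[nm]])
      else num_mat[i, nm] <- as.numeric(resp[[nm]])
    }
    row <- cmp_matrix[[s]][tc, ]
    comparator[i] <- sample(names(row), 1L, prob = row)
  }

  df <- data.frame(
    record_id = rec_id,
    live_birth = rep("yes", n),
    age_at_death_days = age,
    questionnaire_type = ifelse(stratum == "neonate", "neonatal", "child"),
    interview_complete = rep("yes", n),
    survey_weight = weight,
    stratum_id = des_stratum,
    psu_id = des_psu,
    comparator_cause = comparator,
    stringsAsFactors = FALSE
  )
  for (b in bin_items) df[[b]] <- bin_mat[, b]
  for (m in num_items) df[[m]] <- num_mat[, m]
  if (n == 0L) {
    df <- df[0, , drop = FALSE]
  }
  list(
    records = va_records(df, codebook),
    truth = data.frame(record_id = rec_id, stratum = stratum,
                       true_cause = true_cause, weight = weight,
                       stringsAsFactors = FALSE)
  )
}

# Printed study sizes and algorithm-derived CSMFs (per cent of all
# under-five deaths) of the three re-analyzed national VA studies; used as
# *scenario parameters* for simulation, not as reproduction targets.
STUDY_PARAMS <- list(
  uganda = list(
    n = 530L, n_neonatal = 126L,
    neonate = c(pneumonia = 2.8, intrapartum = 6.7, preterm = 5.9,
                congenital = 1.8, sepsis = 0.4, other_neonatal = 2.5,
                tetanus = 2.3, diarrhea = 0.2, unspecified = 2.1),
    child = c(diarrhea = 15.7, malaria = 23.2, aids = 3.9, injury = 2.8,
              meningitis = 1.8, measles = 1.6, other_infections = 2.0,
              pneumonia = 18.3, unspecified = 6.1)
  ),
  rwanda = list(
    n = 360L, n_neonatal = 121L,
    neonate = c(pneumonia = 4.4, intrapartum = 10.7, preterm = 4.5,
                congenital = 1.9, sepsis = 0.5, other_neonatal = 1.5,
                tetanus = 0.9, diarrhea = 0.6, unspecified = 7.2),
    child = c(diarrhea = 11.4, malaria = 25.6, aids = 3.0, injury = 1.2,
              meningitis = 1.2, measles = 0.2, other_infections = 3.3,
              pneumonia = 12.1, unspecified = 9.6)
  ),
  ghana = list(
    n = 188L, n_neonatal = 71L,
    neonate = c(pneumonia = 3.7, intrapartum = 6.4, preterm = 6.3,
                congenital = 3.6, sepsis = 0, other_neonatal = 1.8,
                tetanus = 0.7, diarrhea = 0.0, unspecified = 13.6),
    child = c(diarrhea = 2.5, malaria = 16.8, aids = 8.6, injury = 3.7,
              meningitis = 1.8, measles = 0.5, other_infections = 3.7,
              pneumonia = 14.9, unspecified = 11.4)
  )
)

#' Scenario emulating one of the three re-analyzed national VA studies
#'
#' Sample size and neonatal/post-neonatal split are the published ones
#' (Uganda 530 deaths, 126 neonatal; Rwanda 360/121; Ghana 188/71); the
#' true CSMFs are the published algorithm-derived fractions, renormalized
#' within each age stratum. These serve as simulation parameters with
#' known truth — the original microdata are not redistributable, so the
#' published fractions are inputs here, not targets.
#'
#' @param country `"uganda"`, `"rwanda"` or `"ghana"`.
#' @param ... Overrides passed on to [simulation_scenario()] (e.g.
#'   `sensitivity`, `seed`, or a larger `n` for calibration runs).
#' @return A [simulation_scenario()].
#' @export
scenario_from_paper <- function(country = c("uganda", "rwanda", "ghana"),
                                ...) {
  country <- match.arg(country)
  sp <- STUDY_PARAMS[[country]]
  args <- list(...)
  base <- list(n = sp$n, p_neonatal = sp$n_neonatal / sp$n,
               csmf_neonate = sp$neonate / sum(sp$neonate),
               csmf_child = sp$child / sum(sp$child))
  do.call(simulation_scenario, modifyList(base, args))
}
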