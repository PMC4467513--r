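# Individual-level agreement (per-cause Cohen's kappa) and
# population-level comparison between the algorithm and a second coder.

#' Build paired labels for agreement analysis
#'
#' Records provisionally assigned to more than one cause (the
#' measles/diarrhea/ARI group) *before* redistribution are excluded, as
#' are records lacking a comparator cause. Kappa is computed on
#' unweighted individual records.
#'
#' @param assignments A `va_assignments` table (from [va_assign()]; the
#'   pre-redistribution provisional sets are what matters, so either the
#'   raw table or `va_redistribute()$assignments` may be passed as long as
#'   the `provisional` column is intact).
#' @param records The matching [va_records()] with a `comparator_cause`
#'   column, or a named character vector `record_id -> comparator cause`.
#' @param stratum Optional filter: `"neonate"` or `"child"`.
#' @return A `paired_labels` data.frame: `record_id`, `stratum`,
#'   `algorithm`, `comparator`.
#' @export
exclude_multicause <- function(assignments, records, stratum = NULL) {
  stopifnot(inherits(assignments, "va_assignments") ||
              is.data.frame(assignments))
  if (is.data.frame(records)) {
    if (is.null(records$comparator_cause)) {
      stop("records carry no comparator_cause column", call. = FALSE)
    }
    comp <- setNames(records$comparator_cause, records$record_id)
  } else {
    comp <- records
  }
  multi <- lengths(assignments$provisional) > 1L
  keep <- !multi & !is.na(assignments$final_cause)
  out <- data.frame(record_id = assignments$record_id[keep],
                    stratum = assignments$stratum[keep],
                    algorithm = assignments$final_cause[keep],
                    comparator = unname(comp[assignments$record_id[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$comparator), , drop = FALSE]
  if (!is.null(stratum)) out <- out[out$stratum == stratum, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_labels", "data.frame")
  out
}

# kappa and its large-sample SE (Fleiss, Cohen & Everitt variance) from a
# contingency table of integer counts. All intermediates are kept as
# scaled integers (exactly representable in doubles for any realistic n),
# so results carry no cumulative rounding: O = n*po, E = n^2*pe,
# Ti = n^2*[(1-pe) - (p.i + pi.)(1-po)], etc.
kappa_from_counts <- function(cnt, n) {
  O <- sum(diag(cnt))
  rs <- rowSums(cnt)
  cs <- colSums(cnt)
  E <- sum(rs * cs)
  denom <- n * n - E            # n^2 * (1 - pe)
  if (denom <= 0) {
    # expected agreement 1: both coders constant; kappa degenerate
    return(list(kappa = 0, se = 0, degenerate = TRUE))
  }
  kap <- (n * O - E) / denom
  Ti <- denom - (cs + rs) * (n - O)
  a_term <- sum(diag(cnt) * Ti^2)                      # n^5 * A
  b_term <- 0
  q <- nrow(cnt)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i != j) b_term <- b_term + cnt[i, j] * (cs[i] + rs[j])^2
    }
  }
  b_term <- (n - O)^2 * b_term                         # n^5 * B
  c_term <- (O * E - 2 * E * n + O * n * n)^2          # n^6 * C
  v <- (n * (a_term + b_term) - c_term) * n / denom^4
  list(kappa = kap, se = sqrt(max(v, 0)), degenerate = FALSE)
}

#' Per-cause Cohen's kappa with standard error
#'
#' Both coders are binarized as `cause` vs not-`cause`;
#' `kappa = (p_o - p_e) / (1 - p_e)` with the usual observed and
#' chance-expected agreement, and the large-sample (Fleiss--Cohen--Everitt)
#' standard error. When expected agreement is 1 — e.g. neither coder ever
#' assigns the cause — kappa is degenerate and reported as 0 with SE 0 and
#' `degenerate = TRUE` (the "0.00 (0.000)" convention).
#'
#' @param labels A `paired_labels` data.frame (see [exclude_multicause()])
#'   or any data.frame with `algorithm` and `comparator` columns.
#' @param cause Cause label to binarize on.
#' @return List of class `kappa_result`: `cause`, `kappa`, `se`, `n`,
#'   `degenerate`.
#' @export
cohen_kappa <- function(labels, cause) {
  a <- labels$algorithm
  b <- labels$comparator
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired records", call. = FALSE)
  ya <- a == cause
  yb <- b == cause
  counts <- matrix(c(sum(ya & yb), sum(ya & !yb),
                     sum(!ya & yb), sum(!ya & !yb)),
                   2, 2, byrow = TRUE)
  res <- kappa_from_counts(counts, n)
  structure(list(cause = cause, kappa = res$kappa, se = res$se, n = n,
                 degenerate = res$degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa[%s] = %.2f (%.3f)%s, n = %d\n", x$cause, x$kappa,
              x$se, if (x$degenerate) "*" else "", x$n))
  invisible(x)
}

#' Kappa for every cause, in a report-shaped table
#'
#' @param labels A `paired_labels` data.frame.
#' @param causes Causes to report; defaults to all labels either coder
#'   used.
#' @return data.frame (`cause`, `kappa`, `se`, `degenerate`, `n`).
#' @export
kappa_table <- function(labels, causes = NULL) {
  causes <- causes %||%
    sort(unique(c(labels$algorithm, labels$comparator)))
  rows <- lapply(causes, function(cz) {
    k <- cohen_kappa(labels, cz)
    data.frame(cause = cz, kappa = k$kappa, se = k$se,
               degenerate = k$degenerate, n = k$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Population-level comparison of two CSMF tables
#'
#' Per-cause CSMF differences (percentage points) plus a comparison of the
#' top-`k` single-cause rankings: shared causes, and the rank shift for
#' causes appearing in both lists.
#'
#' @param table_a,table_b `csmf_table`s over the same age group and cause
#'   vocabulary (causes with fraction 0 may be absent from either).
#' @param k Ranking depth (default 5).
#' @param hierarchy_order Optional tie-break order for [rank_top()].
#' @return List of class `csmf_comparison`: `deltas` (data.frame `cause`,
#'   `fraction_a`, `fraction_b`, `delta_pp`), `top_a`, `top_b`,
#'   `overlap` (count of shared top-k causes), `rank_shifts`.
#' @export
compare_populations <- function(table_a, table_b, k = 5,
                                hierarchy_order = NULL) {
  stopifnot(inherits(table_a, "csmf_table"), inherits(table_b, "csmf_table"))
  if (!identical(attr(table_a, "age_group"), attr(table_b, "age_group"))) {
    stop("tables cover different age groups", call. = FALSE)
  }
  causes <- union(table_a$cause, table_b$cause)
  fa <- setNames(rep(0, length(causes)), causes)
  fb <- fa
  fa[table_a$cause] <- table_a$fraction
  fb[table_b$cause] <- table_b$fraction
  # a cause entirely absent from one table is only tolerated at fraction 0
  only_a <- setdiff(table_a$cause[table_a$fraction > 0], table_b$cause)
  only_b <- setdiff(table_b$cause[table_b$fraction > 0], table_a$cause)
  if (length(only_a) || length(only_b)) {
    stop("cause vocabulary mismatch: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  deltas <- data.frame(cause = causes, fraction_a = unname(fa),
                       fraction_b = unname(fb),
                       delta_pp = unname(100 * (fa - fb)),
                       stringsAsFactors = FALSE)
  top_a <- rank_top(table_a, k, hierarchy_order)
  top_b <- rank_top(table_b, k, hierarchy_order)
  shared <- intersect(top_a$cause, top_b$cause)
  shifts <- data.frame(
    cause = shared,
    rank_a = match(shared, top_a$cause),
    rank_b = match(shared, top_b$cause),
    stringsAsFactors = FALSE
  )
  shifts$shift <- shifts$rank_b - shifts$rank_a
  structure(list(deltas = deltas, top_a = top_a, top_b = top_b,
                 overlap = length(shared), rank_shifts = shifts),
            class = "csmf_comparison")
}

#' @export
print.csmf_comparison <- function(x, ...) {
  cat("<csmf_comparison> top-", nrow(x$top_a), " overlap: ", x$overlap,
      "/", nrow(x$top_a), "\n", sep = "")
  cat("max |delta|: ",
      sprintf("%.1f pp", max(abs(x$deltas$delta_pp))), "\n", sep = "")
  invisible(x)
}
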