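# Survey-weighted cause-specific mortality fractions.
#
# CSMF(cause) = sum of allocated survey weight of the cause / total weight
# in the age group. Standard errors (optional) use Taylor linearization of
# the ratio estimator with with-replacement sampling of PSUs within
# strata, i.e. the standard complex-survey variance of a weighted
# proportion.

#' Compute a CSMF table from resolved allocations
#'
#' @param allocation A `va_allocation` from [va_redistribute()].
#' @param records The matching [va_records()] table (provides `stratum_id`
#'   and `psu_id` for the design when `se = TRUE`).
#' @param age_group `"neonate"`, `"child"` or `"all"` (0--59 months
#'   pooled).
#' @param se Compute linearized standard errors?
#' @return A `csmf_table` data.frame (`cause`, `fraction`, optionally
#'   `se`), ordered by the causes' first appearance, with attributes
#'   `age_group` and `n` (unweighted deaths in the age group). Fractions
#'   sum to 1 (unspecified included).
#' @export
compute_csmf <- function(allocation, records, age_group = c("all", "neonate",
                                                            "child"),
                         se = FALSE) {
  age_group <- match.arg(age_group)
  stopifnot(inherits(allocation, "va_allocation"))
  alloc <- allocation$allocations
  if (age_group != "all") {
    alloc <- alloc[alloc$stratum == age_group, , drop = FALSE]
  }
  if (nrow(alloc) == 0L) {
    stop("no records in age group '", age_group, "'", call. = FALSE)
  }
  alloc$alloc_w <- alloc$weight * alloc$fraction
  tot <- sum(unique(data.frame(id = alloc$record_id,
                               w = alloc$weight))$w)
  causes <- unique(alloc$cause)
  frac <- vapply(causes, function(cz) {
    sum(alloc$alloc_w[alloc$cause == cz]) / tot
  }, 0)
  out <- data.frame(cause = causes, fraction = unname(frac),
                    stringsAsFactors = FALSE)

  if (se) {
    idx <- match(alloc$record_id, records$record_id)
    if (anyNA(idx)) stop("allocations reference unknown records",
                         call. = FALSE)
    des_str <- records$stratum_id[idx]
    des_psu <- records$psu_id[idx]
    if (anyNA(des_str) || anyNA(des_psu)) {
      stop("stratum_id/psu_id must be non-missing for SE estimation",
           call. = FALSE)
    }
    psu_key <- paste(des_str, des_psu, sep = "\r")
    out$se <- vapply(seq_along(causes), function(k) {
      ind <- as.numeric(alloc$cause == causes[k]) * alloc$fraction
      # linearized variate of the ratio estimator, per allocation row
      u <- alloc$weight * (ind - frac[k]) / tot
      u_psu <- tapply(u, psu_key, sum)                 # PSU totals
      str_psu <- vapply(strsplit(names(u_psu), "\r", fixed = TRUE),
                        `[`, "", 1L)
      v <- 0
      for (h in unique(str_psu)) {
        uh <- u_psu[str_psu == h]
        nh <- length(uh)
        # single-PSU strata are treated as certainty units (no contribution)
        if (nh >= 2L) v <- v + nh / (nh - 1) * sum((uh - mean(uh))^2)
      }
      sqrt(v)
    }, 0)
  }
  structure(out, age_group = age_group,
            n = length(unique(alloc$record_id)),
            class = c("csmf_table", "data.frame"))
}

#' @export
print.csmf_table <- function(x, digits = 3, ...) {
  cat("<csmf_table> age group: ", attr(x, "age_group"),
      ", n = ", attr(x, "n"), " deaths\n", sep = "")
  print.data.frame(cbind(x["cause"],
                         round(x[setdiff(names(x), "cause")], digits)),
                   row.names = FALSE)
  invisible(x)
}

#' Default mapping from algorithm causes to CHERG-style categories
#'
#' Neonatal causes map to pneumonia, preterm birth complications,
#' intrapartum-related complications (including birth asphyxia and birth
#' injury), sepsis, tetanus, congenital abnormalities, diarrhea and other
#' neonatal disorders; child causes to pneumonia, diarrhea, measles,
#' injury, malaria, AIDS, meningitis and other infections.
#'
#' @return Named character vector, algorithm cause -> category.
#' @export
default_cause_map <- function() {
  c(tetanus = "tetanus",
    congenital = "congenital abnormalities",
    intrapartum = "intrapartum-related complications",
    birth_asphyxia = "intrapartum-related complications",
    birth_injury = "intrapartum-related complications",
    preterm = "preterm birth complications",
    sepsis = "sepsis",
    other_neonatal = "other neonatal disorders",
    pneumonia = "pneumonia",
    diarrhea = "diarrhea",
    measles = "measles",
    injury = "injury",
    meningitis = "meningitis",
    malaria = "malaria",
    aids = "AIDS",
    other_infections = "other infections",
    unspecified = "unspecified")
}

#' Collapse a CSMF table into mapped cause categories
#'
#' @param table A `csmf_table`.
#' @param cmap Named character vector mapping every cause present in the
#'   table to a category (see [default_cause_map()]); the mapping must be
#'   total over the table's causes.
#' @return A `csmf_table` over categories; the total fraction is preserved
#'   exactly. Standard errors, being nonlinear under aggregation, are
#'   dropped.
#' @export
map_causes <- function(table, cmap = default_cause_map()) {
  stopifnot(inherits(table, "csmf_table"))
  unmapped <- setdiff(table$cause, names(cmap))
  if (length(unmapped)) {
    stop("cause(s) without a category mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  cat_of <- unname(cmap[table$cause])
  cats <- unique(cat_of)
  frac <- vapply(cats, function(cc) sum(table$fraction[cat_of == cc]), 0)
  structure(data.frame(cause = cats, fraction = unname(frac),
                       stringsAsFactors = FALSE),
            age_group = attr(table, "age_group"), n = attr(table, "n"),
            class = c("csmf_table", "data.frame"))
}

#' Rank the top-k single causes of a CSMF table
#'
#' Residual categories (by default `"unspecified"` and any cause whose
#' label starts with `"other"`) are not single causes and are excluded
#' from ranking. Ties are broken by hierarchy order when supplied, then
#' lexicographically.
#'
#' @param table A `csmf_table`.
#' @param k Number of ranks requested (>= 1); fewer are returned when the
#'   table has fewer non-zero single causes.
#' @param hierarchy_order Optional character vector giving the evaluation
#'   order used for tie-breaking.
#' @param exclude Labels (or `"other*"` prefixes) treated as residual.
#' @return data.frame (`rank`, `cause`, `fraction`).
#' @export
rank_top <- function(table, k = 5, hierarchy_order = NULL,
                     exclude = c("unspecified", "other")) {
  stopifnot(inherits(table, "csmf_table"), k >= 1)
  residual <- table$cause %in% exclude |
    grepl("^other", table$cause, ignore.case = TRUE) |
    tolower(table$cause) %in% tolower(exclude)
  tab <- table[!residual & table$fraction > 0, , drop = FALSE]
  tie <- match(tab$cause, hierarchy_order %||% character())
  tie[is.na(tie)] <- length(hierarchy_order) + 1L
  ord <- order(-tab$fraction, tie, tab$cause)
  tab <- tab[ord, , drop = FALSE]
  k <- min(k, nrow(tab))
  data.frame(rank = seq_len(k), cause = tab$cause[seq_len(k)],
             fraction = tab$fraction[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Write a CSMF table to CSV or JSON
#' @param table A `csmf_table`.
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_csmf <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(age_group = attr(table, "age_group"), n = attr(table, "n"),
           csmf = as.data.frame(table)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}
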