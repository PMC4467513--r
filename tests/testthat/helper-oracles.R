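# Shared fixtures and independent oracles used across test files.

# --- tiny codebook + records built in code -------------------------------

tiny_codebook <- function() {
  va_codebook(list(
    symptom_item("fever", "binary"),
    symptom_item("cough", "binary"),
    symptom_item("rash", "binary"),
    symptom_item("stools_per_day", "count"),
    symptom_item("cough_days", "duration_days"),
    symptom_item("colour", "categorical", allowed_values = c("red", "blue"))
  ))
}

base_record <- function(id = "r1", age = 100, weight = 1,
                        q = NULL, live = "yes", ...) {
  resp <- list(...)
  df <- data.frame(record_id = id, live_birth = live,
                   age_at_death_days = age,
                   questionnaire_type = q %||%
                     ifelse(age <= 27, "neonatal", "child"),
                   survey_weight = weight,
                   stratum_id = "S1", psu_id = "P1",
                   stringsAsFactors = FALSE)
  for (nm in names(resp)) df[[nm]] <- resp[[nm]]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force predicate interpreter (independent of eval_predicate) ---

naive_eval <- function(p, resp) {
  get1 <- function(it) {
    v <- resp[[it]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NULL else v
  }
  if (p$kind == "item_equals") {
    v <- get1(p$item)
    return(!is.null(v) && as.character(v) == p$value)
  }
  if (p$kind == "item_at_least") {
    v <- get1(p$item)
    return(!is.null(v) && is.numeric(v) && v >= p$min_count)
  }
  if (p$kind == "duration_in_days") {
    v <- get1(p$item)
    return(!is.null(v) && is.numeric(v) &&
             v >= p$min_days && v <= p$max_days)
  }
  vals <- sapply(p$children, naive_eval, resp)
  if (p$kind == "all_of") return(all(vals))
  if (p$kind == "any_of") return(any(vals))
  if (p$kind == "none_of") return(!any(vals))
  stop("bad kind")
}

# random predicate tree over yes-coded binary items plus one count and one
# duration item
random_predicate <- function(items, depth = 3) {
  if (depth == 0 || runif(1) < 0.4) {
    kind <- sample(c("eq", "cnt", "dur"), 1, prob = c(0.7, 0.15, 0.15))
    if (kind == "eq") return(p_item_equals(sample(items, 1), "yes"))
    if (kind == "cnt") return(p_item_at_least("stools_per_day",
                                              sample(0:8, 1)))
    lo <- sample(0:20, 1)
    return(p_duration("cough_days", lo, lo + sample(0:20, 1)))
  }
  comb <- sample(c(p_all, p_any, p_none), 1)[[1]]
  do.call(comb, lapply(seq_len(sample(1:3, 1)), function(i) {
    random_predicate(items, depth - 1)
  }))
}

random_responses <- function(items) {
  resp <- lapply(items, function(i) {
    sample(c("yes", "no", NA_character_), 1)
  })
  names(resp) <- items
  resp$stools_per_day <- sample(c(NA, 0:8), 1)
  resp$cough_days <- sample(c(NA, 0:40), 1)
  resp
}

# --- naive assignment oracle: evaluate everything, then resolve ----------
# If the earliest true cause is outside the multi-cause group it wins
# alone; otherwise every true group member is provisionally assigned;
# nothing true -> fallback.
naive_assign <- function(responses, hierarchy, defs) {
  fired <- Filter(function(cz) {
    eval_predicate(defs[[cz]]$predicate, responses)
  }, hierarchy$ordered_causes)
  if (length(fired) == 0) return(hierarchy$fallback_cause)
  first <- fired[[1]]
  if (!first %in% hierarchy$multi_cause_group) return(first)
  intersect(fired, hierarchy$multi_cause_group)
}

# --- kappa oracle: direct cell-wise arithmetic from 2x2 counts -----------
# a = both assign the cause, b = only coder 1, c = only coder 2, d = neither.
# Written out per cell in scaled-integer form (every intermediate is an
# exact integer for small tables): O = n*po, E = n^2*pe, etc.
kappa_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  O <- a + d
  r1 <- a + b; r2 <- c + d       # coder 1 margins
  c1 <- a + c; c2 <- b + d       # coder 2 margins
  E <- r1 * c1 + r2 * c2
  denom <- n * n - E             # n^2 * (1 - pe)
  if (denom <= 0) {
    return(list(kappa = 0, se = 0, degenerate = TRUE))
  }
  k <- (n * O - E) / denom
  # Fleiss-Cohen-Everitt large-sample variance, cell by cell
  T1 <- denom - (c1 + r1) * (n - O)
  T2 <- denom - (c2 + r2) * (n - O)
  A <- a * T1^2 + d * T2^2                          # n^5 * A-term
  B <- (n - O)^2 * (b * (c1 + r2)^2 + c * (c2 + r1)^2)
  C <- (O * E - 2 * E * n + O * n * n)^2            # n^6 * C-term
  list(kappa = k,
       se = sqrt(max((n * (A + B) - C) * n / denom^4, 0)),
       degenerate = FALSE)
}

# paired labels from 2x2 counts
labels_from_counts <- function(a, b, c, d, cause = "x", other = "y") {
  data.frame(
    algorithm = c(rep(cause, a + b), rep(other, c + d)),
    comparator = c(rep(cause, a), rep(other, b),
                   rep(cause, c), rep(other, d)),
    stringsAsFactors = FALSE
  )
}
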