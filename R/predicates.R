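# Declarative boolean predicate trees over symptom responses.
#
# Leaves test one item (equality, count threshold, duration window);
# combinators are all_of / any_of / none_of. Missing responses ("don't
# know", unanswered) count as symptom-absent: every leaf evaluates FALSE on
# a missing response, so negation via none_of is the only way missingness
# can satisfy a condition.

new_predicate <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "va_predicate")
}

#' Predicate constructors
#'
#' Build the nodes of a case-definition predicate tree.
#' `p_item_equals(item, value)` is true iff the response is non-missing and
#' equals `value` (binary items use `"yes"`/`"no"`). `p_item_at_least`
#' tests a count item against a minimum. `p_duration` tests a
#' duration-in-days item against a closed interval `[min_days, max_days]`
#' (use `max_days = Inf` for open-ended windows such as "> 30 days", i.e.
#' `min_days = 31`). `p_all`, `p_any`, `p_none` combine child predicates;
#' `p_none(x)` is true iff no child is true.
#'
#' @param item Codebook item id (string).
#' @param value Response value to match.
#' @param min_count Minimum count (inclusive).
#' @param min_days,max_days Closed duration window in whole days.
#' @param ... Child predicates.
#' @return A `va_predicate` node.
#' @name predicates
NULL

#' @rdname predicates
#' @export
p_item_equals <- function(item, value = "yes") {
  stopifnot(is.character(item), length(item) == 1L)
  new_predicate("item_equals", item = item, value = as.character(value))
}

#' @rdname predicates
#' @export
p_item_at_least <- function(item, min_count) {
  stopifnot(is.character(item), length(item) == 1L,
            is.numeric(min_count), min_count >= 0)
  new_predicate("item_at_least", item = item, min_count = min_count)
}

#' @rdname predicates
#' @export
p_duration <- function(item, min_days, max_days = Inf) {
  stopifnot(is.numeric(min_days), is.numeric(max_days))
  if (min_days > max_days) {
    stop("duration window has min_days > max_days", call. = FALSE)
  }
  new_predicate("duration_in_days", item = item,
                min_days = min_days, max_days = max_days)
}

combinator <- function(kind, children) {
  if (length(children) == 0L) {
    stop(kind, " needs at least one child predicate", call. = FALSE)
  }
  stopifnot(all(vapply(children, inherits, TRUE, "va_predicate")))
  new_predicate(kind, children = children)
}

#' @rdname predicates
#' @export
p_all <- function(...) combinator("all_of", list(...))

#' @rdname predicates
#' @export
p_any <- function(...) combinator("any_of", list(...))

#' @rdname predicates
#' @export
p_none <- function(...) combinator("none_of", list(...))

#' Evaluate a predicate tree on one record's responses
#'
#' Pure and deterministic; missing responses never satisfy a leaf.
#'
#' @param predicate A `va_predicate`.
#' @param responses Named list (or one-row data.frame slice) of responses:
#'   character for binary/categorical items, numeric for counts/durations.
#' @return `TRUE` or `FALSE`.
#' @export
eval_predicate <- function(predicate, responses) {
  stopifnot(inherits(predicate, "va_predicate"))
  switch(predicate$kind,
    item_equals = {
      v <- responses[[predicate$item]]
      length(v) == 1L && !is.na(v) && as.character(v) == predicate$value
    },
    item_at_least = {
      v <- responses[[predicate$item]]
      length(v) == 1L && !is.na(v) && is.numeric(v) &&
        v >= predicate$min_count
    },
    duration_in_days = {
      v <- responses[[predicate$item]]
      length(v) == 1L && !is.na(v) && is.numeric(v) &&
        v >= predicate$min_days && v <= predicate$max_days
    },
    all_of = all(vapply(predicate$children, eval_predicate, TRUE, responses)),
    any_of = any(vapply(predicate$children, eval_predicate, TRUE, responses)),
    none_of = !any(vapply(predicate$children, eval_predicate, TRUE,
                          responses)),
    stop("unknown predicate kind: ", predicate$kind, call. = FALSE)
  )
}

#' Item ids referenced by a predicate tree
#' @param predicate A `va_predicate`.
#' @return Character vector of distinct item ids (leaves only).
#' @export
predicate_items <- function(predicate) {
  stopifnot(inherits(predicate, "va_predicate"))
  if (predicate$kind %in% c("all_of", "any_of", "none_of")) {
    unique(unlist(lapply(predicate$children, predicate_items)))
  } else {
    predicate$item
  }
}

# Configuration-time validation: every leaf must name a codebook item of a
# compatible kind. Errors carry the path to the offending node.
validate_predicate <- function(predicate, codebook, where = "predicate") {
  if (!inherits(predicate, "va_predicate")) {
    stop(where, ": not a predicate", call. = FALSE)
  }
  if (predicate$kind %in% c("all_of", "any_of", "none_of")) {
    for (i in seq_along(predicate$children)) {
      validate_predicate(predicate$children[[i]], codebook,
                         paste0(where, "/", predicate$kind, "[", i, "]"))
    }
    return(invisible(TRUE))
  }
  it <- codebook[[predicate$item]]
  if (is.null(it)) {
    stop(where, ": item '", predicate$item, "' not in codebook",
         call. = FALSE)
  }
  need <- switch(predicate$kind,
                 item_equals = c("binary", "categorical"),
                 item_at_least = "count",
                 duration_in_days = "duration_days")
  if (!it$kind %in% need) {
    stop(where, ": item '", predicate$item, "' has kind '", it$kind,
         "', incompatible with ", predicate$kind, call. = FALSE)
  }
  invisible(TRUE)
}

# Serialization: predicates round-trip losslessly through plain nested
# lists (hence YAML/JSON).
predicate_to_list <- function(predicate) {
  stopifnot(inherits(predicate, "va_predicate"))
  switch(predicate$kind,
    item_equals = list(item_equals = list(item = predicate$item,
                                          value = predicate$value)),
    item_at_least = list(item_at_least = list(item = predicate$item,
                                              min_count = predicate$min_count)),
    duration_in_days = list(duration_in_days = list(
      item = predicate$item,
      min_days = predicate$min_days,
      max_days = if (is.finite(predicate$max_days)) predicate$max_days
                 else ".inf"
    )),
    list(
      setNames(list(lapply(predicate$children, predicate_to_list)),
               predicate$kind)
    )[[1]]
  )
}

predicate_from_list <- function(x, where = "predicate") {
  if (!is.list(x) || length(x) != 1L || is.null(names(x))) {
    stop(where, ": each predicate node must be a single-key map",
         call. = FALSE)
  }
  kind <- names(x)
  body <- x[[1]]
  switch(kind,
    item_equals = p_item_equals(body$item, body$value %||% "yes"),
    item_at_least = p_item_at_least(body$item, as.numeric(body$min_count)),
    duration_in_days = {
      mx <- body$max_days %||% Inf
      if (identical(mx, ".inf") || identical(mx, "Inf")) mx <- Inf
      p_duration(body$item, as.numeric(body$min_days), as.numeric(mx))
    },
    all_of = ,
    any_of = ,
    none_of = {
      if (length(body) == 0L) {
        stop(where, ": empty ", kind, call. = FALSE)
      }
      combinator(kind, lapply(seq_along(body), function(i) {
        predicate_from_list(body[[i]], paste0(where, "/", kind, "[", i, "]"))
      }))
    },
    stop(where, ": unknown predicate kind '", kind, "'", call. = FALSE)
  )
}
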