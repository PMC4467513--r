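# Codebook: the dictionary of questionnaire items a VA record may carry.

#' Define one symptom/sign questionnaire item
#'
#' @param id Item identifier (string, unique within a codebook).
#' @param kind One of `"binary"` (yes/no), `"count"` (non-negative integer,
#'   e.g. stools per day), `"duration_days"` (non-negative integer number of
#'   days), `"categorical"` (one of `allowed_values`).
#' @param allowed_values For `categorical` items, the permitted codes.
#'   Binary items always permit `"yes"`/`"no"`.
#' @param missing_codes Raw codes mapped to missing on load (besides empty
#'   cells and `NA`). Defaults to the conventional don't-know codes.
#' @param label Optional human-readable label.
#' @return An object of class `symptom_item`.
#' @export
symptom_item <- function(id, kind = c("binary", "count", "duration_days",
                                      "categorical"),
                         allowed_values = NULL,
                         missing_codes = c("9", "99", "dk", "DK"),
                         label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (kind == "categorical" && length(allowed_values) == 0L) {
    stop("categorical item '", id, "' needs allowed_values", call. = FALSE)
  }
  if (kind == "binary") allowed_values <- c("yes", "no")
  structure(
    list(id = id, kind = kind,
         allowed_values = allowed_values,
         missing_codes = as.character(missing_codes),
         label = label %||% id),
    class = "symptom_item"
  )
}

#' Build a codebook from symptom items
#'
#' @param items List of [symptom_item()] objects.
#' @return Object of class `va_codebook`: a named list of items keyed by id.
#' @export
va_codebook <- function(items) {
  stopifnot(is.list(items), all(vapply(items, inherits, TRUE, "symptom_item")))
  ids <- vapply(items, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate item ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(setNames(items, ids), class = "va_codebook")
}

#' @export
print.va_codebook <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat("<va_codebook> ", length(x), " items (",
      paste(sprintf("%s: %d", names(table(kinds)), as.integer(table(kinds))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Item ids of a codebook
#' @param codebook A [va_codebook()].
#' @return Character vector of item ids.
#' @export
codebook_ids <- function(codebook) {
  stopifnot(inherits(codebook, "va_codebook"))
  names(codebook)
}

#' The default under-five VA codebook
#'
#' Items cover the sign/symptom vocabulary used by the shipped case
#' definitions: general infection signs (fever, convulsions, neck
#' stiffness...), respiratory signs with durations, diarrhea with stool
#' counts and duration, rash, the wasting-type signs used by the AIDS
#' screen, injury items, and perinatal items for the neonatal hierarchy.
#'
#' @return A [va_codebook()].
#' @export
builtin_codebook <- function() {
  bin <- function(id, label = NULL) symptom_item(id, "binary", label = label)
  dur <- function(id) symptom_item(id, "duration_days")
  cnt <- function(id) symptom_item(id, "count")
  va_codebook(list(
    # general
    bin("fever"), dur("fever_duration_days"),
    bin("convulsions"), bin("unconscious"),
    bin("stiff_neck"), bin("bulging_fontanelle"),
    # respiratory
    bin("cough"), dur("cough_duration_days"),
    bin("trouble_breathing"), dur("breathing_duration_days"),
    bin("fast_breathing"), bin("chest_indrawing"),
    # gastro-intestinal
    bin("loose_stools"), dur("diarrhea_duration_days"),
    cnt("stools_per_day"),
    # rash / measles
    bin("rash"), bin("rash_on_face"), dur("rash_duration_days"),
    # AIDS screen components
    bin("jaundice"), bin("paleness"), bin("hair_color_change"),
    bin("edema_legs"), bin("dry_scaly_skin"), bin("tb_diagnosis_recent"),
    # injury
    bin("injury_accident"), bin("road_accident"), bin("fall"),
    bin("drowning"), bin("burn"), bin("poisoning"), bin("animal_bite"),
    # perinatal / neonatal
    bin("born_early"), bin("very_small_at_birth"),
    bin("not_cry_after_birth"), bin("not_breathe_after_birth"),
    bin("suckled_normally_first_2d"), bin("stopped_suckling"),
    bin("spasms"), bin("cold_to_touch"), bin("lethargic"),
    bin("malformation"), bin("malformation_head"), bin("malformation_spine"),
    bin("malformation_limb"), bin("malformation_other")
  ))
}

codebook_to_list <- function(codebook) {
  list(items = lapply(unname(codebook), function(it) {
    out <- list(id = it$id, kind = it$kind)
    if (it$kind == "categorical") out$allowed_values <- as.list(it$allowed_values)
    out$missing_codes <- as.list(it$missing_codes)
    if (!identical(it$label, it$id)) out$label <- it$label
    out
  }))
}

codebook_from_list <- function(x, where = "codebook") {
  if (!is.list(x) || is.null(x$items)) {
    stop(where, ": expected a top-level 'items' list", call. = FALSE)
  }
  va_codebook(lapply(seq_along(x$items), function(i) {
    it <- x$items[[i]]
    if (is.null(it$id) || is.null(it$kind)) {
      stop(where, ": item #", i, " lacks 'id' or 'kind'", call. = FALSE)
    }
    symptom_item(it$id, it$kind,
                 allowed_values = unlist(it$allowed_values),
                 missing_codes = unlist(it$missing_codes) %||%
                   c("9", "99", "dk", "DK"),
                 label = it$label)
  }))
}

#' Read a codebook from YAML or JSON
#'
#' The file must contain a top-level `items` array; each entry has `id`,
#' `kind`, and optionally `allowed_values`, `missing_codes`, `label`. A
#' JSON Schema describing the format ships under
#' `system.file("schema", "codebook.schema.json", package = "vacause")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [va_codebook()].
#' @export
read_codebook <- function(path) {
  codebook_from_list(read_config(path), where = path)
}

#' Write a codebook to YAML
#' @param codebook A [va_codebook()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  yaml::write_yaml(codebook_to_list(codebook), path)
  invisible(path)
}

# Shared config reader: YAML or JSON by extension.
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
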