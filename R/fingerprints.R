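#' Read a binary fingerprint matrix from CSV or TSV
#'
#' The expected layout is one row per compound: the first column holds the
#' compound identifier, the header row of the remaining columns holds the
#' (non-negative integer) bit identifiers, and every cell is 0 or 1.
#' File order of rows and columns is preserved.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @return A tibble whose first column is `compound_id` and whose remaining
#'   columns are integer 0/1 bit columns named by their bit identifiers.
#' @export
#' @examples
#' fp <- tibble::tibble(compound_id = c("a", "b"), `0` = c(1L, 0L), `7` = c(0L, 0L))
#' f <- tempfile(fileext = ".csv")
#' write_bit_matrix(fp, f)
#' read_bit_matrix(f)
read_bit_matrix <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("fingerprint file does not exist: ", path, call. = FALSE)
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2) {
    stop("fingerprint file must have a compound-id column plus at least one bit column",
         call. = FALSE)
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bit_names <- names(raw)[-1]
  bit_ids <- suppressWarnings(as.integer(bit_names))
  if (anyNA(bit_ids) || any(bit_ids < 0)) {
    stop("bit column headers must be non-negative integers; offending: ",
         paste(bit_names[is.na(bit_ids) | bit_ids < 0], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(bit_ids)) {
    stop("duplicate bit id(s) in header: ",
         paste(unique(bit_ids[duplicated(bit_ids)]), collapse = ", "), call. = FALSE)
  }
  cols <- lapply(seq_along(bit_names), function(j) {
    v <- raw[[j + 1L]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad) > 0) {
      stop(sprintf("non-binary cell value %s at row %d (compound %s), bit column %s",
                   dQuote(v[bad[1]]), bad[1], ids[bad[1]], bit_names[j]),
           call. = FALSE)
    }
    as.integer(v)
  })
  names(cols) <- as.character(bit_ids)
  out <- tibble::tibble(compound_id = ids, !!!cols)
  out
}

#' Write a binary fingerprint matrix to CSV or TSV
#'
#' Inverse of [read_bit_matrix()]: `read_bit_matrix(write_bit_matrix(fp, f), f)`
#' reproduces `fp` exactly.
#'
#' @param fingerprints Fingerprint tibble (first column `compound_id`).
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_bit_matrix <- function(fingerprints, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  fp <- validate_fingerprints(fingerprints)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(fingerprints, path, progress = FALSE)
  invisible(path)
}

# Validate a fingerprint tibble and return its pieces as a plain list:
# compound ids, integer bit ids and an integer 0/1 matrix.
validate_fingerprints <- function(fingerprints) {
  stopifnot(is.data.frame(fingerprints))
  if (ncol(fingerprints) < 1 || names(fingerprints)[1] != "compound_id") {
    stop("fingerprint table must start with a `compound_id` column", call. = FALSE)
  }
  ids <- as.character(fingerprints[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bit_names <- names(fingerprints)[-1]
  bit_ids <- suppressWarnings(as.integer(bit_names))
  if (length(bit_ids) > 0 && (anyNA(bit_ids) || any(bit_ids < 0))) {
    stop("bit columns must be named by non-negative integer bit ids", call. = FALSE)
  }
  if (anyDuplicated(bit_ids)) {
    stop("duplicate bit id(s)", call. = FALSE)
  }
  mat <- NULL
  if (length(bit_ids) > 0) {
    mat <- as.matrix(fingerprints[, -1, drop = FALSE])
    storage.mode(mat) <- "integer"
    if (anyNA(mat) || !all(mat == 0L | mat == 1L)) {
      bad <- which(is.na(mat) | !(mat == 0L | mat == 1L), arr.ind = TRUE)[1, ]
      stop(sprintf("non-binary entry at compound %s, bit %s",
                   ids[bad[1]], bit_names[bad[2]]), call. = FALSE)
    }
    dimnames(mat) <- list(ids, as.character(bit_ids))
  }
  list(compound_ids = ids, bit_ids = bit_ids, matrix = mat)
}

# Assemble a fingerprint tibble from an integer 0/1 matrix.
fingerprint_tibble <- function(mat, compound_ids, bit_ids) {
  storage.mode(mat) <- "integer"
  cols <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
  names(cols) <- as.character(bit_ids)
  tibble::tibble(compound_id = as.character(compound_ids), !!!cols)
}

#' Bundle a fingerprint matrix with binary activity labels
#'
#' A labeled dataset is the unit every scoring and selection function
#' consumes: a fingerprint tibble plus one 0/1 label per compound.
#'
#' @param fingerprints Fingerprint tibble (see [read_bit_matrix()]).
#' @param labels Vector of 0/1 labels (or a logical vector), one per row.
#' @param task_id Identifier for the classification task.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(fingerprints, labels, task_id = "task") {
  parts <- validate_fingerprints(fingerprints)
  labels <- as.integer(labels)
  if (length(labels) != length(parts$compound_ids)) {
    stop("labels length (", length(labels), ") does not match row count (",
         length(parts$compound_ids), ")", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  structure(
    list(fingerprints = tibble::as_tibble(fingerprints), labels = labels,
         task_id = as.character(task_id)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> task %s: %d compounds x %d bits (%d positive, %d negative)\n",
              x$task_id, nrow(x$fingerprints), ncol(x$fingerprints) - 1L,
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Split a potency table into active / inactive / discarded compounds
#'
#' Compounds measured against `target` are labelled `active` when their
#' potency (Ki or equivalent, nM) is at or below `active_max_nM`, `inactive`
#' when above `inactive_min_nM`, and `discarded` when it falls in the gap
#' between the two thresholds. Repeated measurements of the same compound
#' against the same target are collapsed to their median potency before
#' thresholding.
#'
#' @param records Data frame with columns `compound_id`, `target_id`,
#'   `potency_nM` (positive, nanomolar).
#' @param target Target id to split on.
#' @param active_max_nM Upper potency bound for actives (default 100 nM).
#' @param inactive_min_nM Lower potency bound (exclusive) for inactives
#'   (default 1000 nM).
#' @return A tibble with columns `compound_id`, `potency_nM` (median) and
#'   `label` in `{"active", "inactive", "discarded"}`; one row per compound.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   compound_id = c("c1", "c2", "c3"), target_id = "5HT1A",
#'   potency_nM = c(50, 500, 5000))
#' split_activity(recs, "5HT1A")
split_activity <- function(records, target,
                           active_max_nM = 100, inactive_min_nM = 1000) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "target_id", "potency_nM") %in% names(records)))
  if (!(active_max_nM < inactive_min_nM)) {
    stop("active_max_nM must be strictly below inactive_min_nM", call. = FALSE)
  }
  if (any(is.na(records$potency_nM)) || any(records$potency_nM <= 0)) {
    stop("potencies must be positive", call. = FALSE)
  }
  if (!target %in% records$target_id) {
    stop("unknown target id: ", target, call. = FALSE)
  }
  records |>
    dplyr::filter(.data$target_id == .env$target) |>
    dplyr::summarise(potency_nM = stats::median(.data$potency_nM),
                     .by = "compound_id") |>
    dplyr::mutate(label = dplyr::case_when(
      .data$potency_nM <= active_max_nM ~ "active",
      .data$potency_nM > inactive_min_nM ~ "inactive",
      TRUE ~ "discarded"
    )) |>
    tibble::as_tibble()
}

#' Build a labeled dataset from a potency table and a fingerprint matrix
#'
#' Convenience wrapper: [split_activity()] then restrict the fingerprint
#' matrix to active (label 1) and inactive (label 0) compounds; discarded
#' compounds and compounds without fingerprints are dropped.
#'
#' @inheritParams split_activity
#' @param fingerprints Fingerprint tibble.
#' @return A [labeled_dataset()].
#' @export
activity_dataset <- function(records, fingerprints, target,
                             active_max_nM = 100, inactive_min_nM = 1000) {
  split <- split_activity(records, target, active_max_nM, inactive_min_nM)
  split <- dplyr::filter(split, .data$label != "discarded")
  keep <- fingerprints$compound_id %in% split$compound_id
  fp <- fingerprints[keep, , drop = FALSE]
  lab <- split$label[match(fp$compound_id, split$compound_id)]
  labeled_dataset(fp, as.integer(lab == "active"), task_id = target)
}
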