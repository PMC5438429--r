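#' Build a pairwise ligand-selectivity task
#'
#' Constructs the A-versus-B discrimination task used in selectivity
#' profiling: actives of `target_a` get label 1, actives of `target_b` label
#' 0, and compounds active at both targets are excluded (a dual-active
#' compound has no well-defined selectivity label) and counted in
#' `excluded_overlap`. Inactives play no role in pair tasks. Alternatively,
#' dual actives can be kept and labelled by their more potent side via
#' `overlap = "by_potency"`.
#'
#' @param actives Data frame with columns `target_id` and `compound_id`
#'   listing the active compounds of every target, or a named list of
#'   compound-id vectors.
#' @param fingerprints Fingerprint tibble covering the active compounds.
#' @param target_a,target_b Distinct target ids.
#' @param overlap `"exclude"` (default) or `"by_potency"`; the latter
#'   requires a `potency_nM` column in `actives` and assigns each dual-active
#'   compound to the target where it is more potent (ties excluded).
#' @return An object of class `pair_task`: `target_a`, `target_b`,
#'   `dataset` (a [labeled_dataset()]) and `excluded_overlap`.
#' @export
build_pair_task <- function(actives, fingerprints, target_a, target_b,
                            overlap = c("exclude", "by_potency")) {
  overlap <- match.arg(overlap)
  actives <- as_actives_table(actives)
  if (identical(target_a, target_b)) {
    stop("target_a and target_b must differ", call. = FALSE)
  }
  set_a <- unique(actives$compound_id[actives$target_id == target_a])
  set_b <- unique(actives$compound_id[actives$target_id == target_b])
  if (length(set_a) == 0) stop("target has no actives: ", target_a, call. = FALSE)
  if (length(set_b) == 0) stop("target has no actives: ", target_b, call. = FALSE)
  both <- intersect(set_a, set_b)
  if (overlap == "by_potency" && length(both) > 0) {
    if (!"potency_nM" %in% names(actives)) {
      stop("overlap = \"by_potency\" requires a potency_nM column", call. = FALSE)
    }
    pot <- actives |>
      dplyr::filter(.data$compound_id %in% both,
                    .data$target_id %in% c(target_a, target_b)) |>
      dplyr::summarise(potency_nM = min(.data$potency_nM),
                       .by = c("compound_id", "target_id")) |>
      tidyr::pivot_wider(names_from = "target_id", values_from = "potency_nM")
    to_a <- pot$compound_id[pot[[target_a]] < pot[[target_b]]]
    to_b <- pot$compound_id[pot[[target_b]] < pot[[target_a]]]
    dropped <- setdiff(both, c(to_a, to_b))   # ties stay excluded
    set_a <- setdiff(set_a, setdiff(both, to_a))
    set_b <- setdiff(set_b, setdiff(both, to_b))
    n_excluded <- length(dropped)
  } else {
    set_a <- setdiff(set_a, both)
    set_b <- setdiff(set_b, both)
    n_excluded <- length(both)
  }
  if (length(set_a) < 2 || length(set_b) < 2) {
    stop(degenerate_pair_condition(target_a, target_b, length(set_a), length(set_b)))
  }
  keep <- fingerprints$compound_id %in% c(set_a, set_b)
  fp <- fingerprints[keep, , drop = FALSE]
  miss_a <- sum(!set_a %in% fp$compound_id)
  miss_b <- sum(!set_b %in% fp$compound_id)
  if (miss_a + miss_b > 0) {
    stop("active compound(s) missing from the fingerprint matrix: ",
         miss_a + miss_b, call. = FALSE)
  }
  labels <- as.integer(fp$compound_id %in% set_a)
  structure(
    list(target_a = target_a, target_b = target_b,
         dataset = labeled_dataset(fp, labels,
                                   task_id = paste0(target_a, "_vs_", target_b)),
         excluded_overlap = n_excluded),
    class = "pair_task"
  )
}

degenerate_pair_condition <- function(a, b, na, nb) {
  structure(
    class = c("aicmax_degenerate_pair", "error", "condition"),
    list(message = sprintf(
      "degenerate pair %s vs %s: %d / %d compounds per class after overlap exclusion (need >= 2 each)",
      a, b, na, nb),
      call = NULL)
  )
}

as_actives_table <- function(actives) {
  if (is.list(actives) && !is.data.frame(actives)) {
    stopifnot(!is.null(names(actives)))
    actives <- purrr::imap_dfr(actives, function(ids, tgt) {
      tibble::tibble(target_id = tgt, compound_id = as.character(ids))
    })
  }
  stopifnot(is.data.frame(actives),
            all(c("target_id", "compound_id") %in% names(actives)))
  actives
}

#' @export
print.pair_task <- function(x, ...) {
  cat(sprintf("<pair_task> %s (label 1) vs %s (label 0): %d compounds, %d dual-active excluded\n",
              x$target_a, x$target_b, nrow(x$dataset$fingerprints),
              x$excluded_overlap))
  invisible(x)
}

#' Run AIC-MAX selection on every unordered target pair
#'
#' Builds the A-versus-B task for each of the C(T, 2) unordered pairs of
#' targets and runs [greedy_select()] on it. Pairs that are degenerate after
#' overlap exclusion (fewer than two compounds in either class) are recorded
#' as skipped, not fatal.
#'
#' @inheritParams build_pair_task
#' @param k Bits to select per pair (default 100).
#' @return An object of class `pairwise_selection`: a tibble `pairs` with
#'   columns `target_a`, `target_b`, `skipped`, `reason`, `excluded_overlap`
#'   and a `result` list-column of `selection_result`s, plus `k` and
#'   `targets`.
#' @export
select_all_pairs <- function(actives, fingerprints, k = 100,
                             overlap = c("exclude", "by_potency")) {
  overlap <- match.arg(overlap)
  actives <- as_actives_table(actives)
  targets <- sort(unique(actives$target_id))
  if (length(targets) < 2) stop("need at least 2 targets", call. = FALSE)
  combos <- utils::combn(targets, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    res <- tryCatch({
      task <- build_pair_task(actives, fingerprints, a, b, overlap = overlap)
      list(skipped = FALSE, reason = NA_character_,
           excluded_overlap = task$excluded_overlap,
           result = list(greedy_select(task$dataset, k = k)))
    }, aicmax_degenerate_pair = function(e) {
      list(skipped = TRUE, reason = conditionMessage(e),
           excluded_overlap = NA_integer_, result = list(NULL))
    })
    tibble::tibble(target_a = a, target_b = b, skipped = res$skipped,
                   reason = res$reason, excluded_overlap = res$excluded_overlap,
                   result = res$result)
  })
  structure(
    list(pairs = dplyr::bind_rows(rows), k = k, targets = targets),
    class = "pairwise_selection"
  )
}

#' @export
print.pairwise_selection <- function(x, ...) {
  cat(sprintf("<pairwise_selection> %d targets, %d pairs (%d skipped), k = %d\n",
              length(x$targets), nrow(x$pairs), sum(x$pairs$skipped), x$k))
  invisible(x)
}

pairs_for_target <- function(results, target) {
  stopifnot(inherits(results, "pairwise_selection"))
  if (!target %in% results$targets) {
    stop("unknown target: ", target, call. = FALSE)
  }
  sub <- dplyr::filter(results$pairs,
                       (.data$target_a == target | .data$target_b == target),
                       !.data$skipped)
  if (nrow(sub) == 0) {
    stop("target participates in no completed pair: ", target, call. = FALSE)
  }
  sub
}

#' Union of selected bits over all pairs involving a target
#'
#' The per-target selectivity vocabulary: every bit selected in at least one
#' pairwise experiment involving `target`.
#'
#' @param results A `pairwise_selection` from [select_all_pairs()].
#' @param target Target id.
#' @return Sorted integer vector of bit ids.
#' @export
union_bits <- function(results, target) {
  sub <- pairs_for_target(results, target)
  sort(unique(unlist(lapply(sub$result, `[[`, "selected"))))
}

#' Bits selected in every pairwise experiment involving a target
#'
#' The per-target core: the intersection of the selected sets over all
#' (non-skipped) pairs involving `target` — bits that discriminate its
#' ligands from those of every other target.
#'
#' @inheritParams union_bits
#' @return Sorted integer vector of bit ids (possibly empty).
#' @export
core_bits <- function(results, target) {
  sub <- pairs_for_target(results, target)
  sets <- lapply(sub$result, `[[`, "selected")
  sort(Reduce(intersect, sets))
}

#' Per-target bit-selection occurrence matrix
#'
#' For one target, tabulates which bits were selected against which
#' off-target: the long form of the black-square occurrence matrices used to
#' visualize pairwise selections.
#'
#' @inheritParams union_bits
#' @return A tibble with columns `bit`, `off_target`, `selected` (0/1),
#'   covering the union bits of `target` against every off-target.
#' @export
occurrence_matrix <- function(results, target) {
  sub <- pairs_for_target(results, target)
  all_bits <- union_bits(results, target)
  purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    off <- if (sub$target_a[i] == target) sub$target_b[i] else sub$target_a[i]
    tibble::tibble(bit = all_bits, off_target = off,
                   selected = as.integer(all_bits %in% sub$result[[i]]$selected))
  })
}

#' Write pairwise selection results to a directory
#'
#' One JSON file per completed pair plus a `manifest.json` recording the run
#' parameters, the pair list, skip records and per-target union/core bits.
#' The per-target occurrence matrices are written as TSV.
#'
#' @inheritParams union_bits
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pairwise_results <- function(results, dir) {
  stopifnot(inherits(results, "pairwise_selection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(results$pairs))
  for (i in seq_len(nrow(results$pairs))) {
    if (results$pairs$skipped[i]) next
    f <- sprintf("pair_%s_vs_%s.json",
                 results$pairs$target_a[i], results$pairs$target_b[i])
    write_selection_json(results$pairs$result[[i]], file.path(dir, f))
    files[i] <- f
  }
  summaries <- lapply(results$targets, function(t) {
    ok <- tryCatch(list(union = union_bits(results, t),
                        core = core_bits(results, t)),
                   error = function(e) list(union = integer(0), core = integer(0)))
    ok
  })
  names(summaries) <- results$targets
  manifest <- list(
    k = results$k,
    targets = results$targets,
    pairs = results$pairs[, c("target_a", "target_b", "skipped", "reason",
                              "excluded_overlap")],
    files = files,
    per_target = summaries,
    tool_version = as.character(utils::packageVersion("aicmax"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (t in results$targets) {
    occ <- tryCatch(occurrence_matrix(results, t), error = function(e) NULL)
    if (!is.null(occ)) {
      wide <- tidyr::pivot_wider(occ, names_from = "off_target",
                                 values_from = "selected")
      readr::write_tsv(wide, file.path(dir, sprintf("occurrence_%s.tsv", t)),
                       progress = FALSE)
    }
  }
  invisible(dir)
}
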