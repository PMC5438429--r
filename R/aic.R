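#' Shannon entropy of a binary label vector
#'
#' H(Y) = -sum_y P(y) log2 P(y) with the convention 0 * log2 0 = 0, so the
#' result lies in \[0, 1\] bits and is 0 for single-class labels.
#'
#' @param labels Vector of 0/1 (or logical) labels.
#' @return Entropy in bits.
#' @export
#' @examples
#' label_entropy(c(1, 1, 0, 0))   # 1
#' label_entropy(c(1, 1, 1, 0))   # 0.8112781
label_entropy <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  p <- mean(labels == 1L)
  entropy2(p)
}

entropy2 <- function(p) {
  terms <- c(p, 1 - p)
  terms <- terms[terms > 0]
  -sum(terms * log2(terms))
}

# ---- internal scoring machinery ---------------------------------------------
#
# Joint patterns over a bit subset are keyed incrementally: a dense pattern
# index (1..m, m <= n_samples) is extended by one bit at a time via
# key = (pat - 1) * 2 + bit + 1 and re-densified, so a score evaluation costs
# O(n_samples) regardless of subset size, never O(2^N).

# Normalized mutual information I(pattern; y) / Hy from a dense pattern index.
nmi_from_pattern <- function(pat, m, y, Hy) {
  n <- length(y)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  nx <- tabulate(pat, m)
  c1 <- tabulate(pat[y == 1L], m)
  c0 <- nx - c1
  mi <- 0
  pos <- which(c1 > 0L)
  if (n1 > 0L && length(pos) > 0) {
    mi <- mi + sum(c1[pos] / n * (log2(c1[pos]) + log2(n) - log2(nx[pos]) - log2(n1)))
  }
  pos <- which(c0 > 0L)
  if (n0 > 0L && length(pos) > 0) {
    mi <- mi + sum(c0[pos] / n * (log2(c0[pos]) + log2(n) - log2(nx[pos]) - log2(n0)))
  }
  a <- mi / Hy
  # guard against floating-point underrun only; genuine violations would be bugs
  if (a < 0) {
    if (a < -1e-12) stop("internal error: negative mutual information", call. = FALSE)
    a <- 0
  }
  if (a > 1) {
    if (a > 1 + 1e-12) stop("internal error: normalized MI above 1", call. = FALSE)
    a <- 1
  }
  a
}

# Dense pattern index for a set of matrix columns.
pattern_index <- function(mat, cols) {
  pat <- rep.int(1L, nrow(mat))
  m <- 1L
  for (j in cols) {
    key <- (pat - 1L) * 2L + mat[, j] + 1L
    dens <- densify(key, 2L * m)
    pat <- dens$pat
    m <- dens$m
  }
  list(pat = pat, m = m)
}

densify <- function(key, nbins) {
  used <- which(tabulate(key, nbins) > 0L)
  map <- integer(nbins)
  map[used] <- seq_along(used)
  list(pat = map[key], m = length(used))
}

# Resolve requested bit ids to column positions of a validated matrix.
resolve_bits <- function(parts, bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0) stop("bit subset must be non-empty", call. = FALSE)
  pos <- match(bits, parts$bit_ids)
  if (anyNA(pos)) {
    stop("bit id(s) not present in matrix: ",
         paste(bits[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  pos
}

check_two_classes <- function(labels, task_id = NULL) {
  if (length(unique(labels)) < 2L) {
    stop("degenerate task", if (!is.null(task_id)) paste0(" `", task_id, "`"),
         ": labels contain a single class (label entropy is zero)",
         call. = FALSE)
  }
  invisible(labels)
}

# ---- user-facing scoring -----------------------------------------------------

#' Empirical joint distribution of a bit-subset's patterns and the label
#'
#' Probabilities are maximum-likelihood relative frequencies over the rows:
#' each compound contributes its observed pattern x (the restriction of its
#' fingerprint to `bits`, in the given order) and its label y. Patterns never
#' observed carry probability zero and are omitted.
#'
#' @param fingerprints Fingerprint tibble.
#' @param bits Integer bit ids (non-empty, all present in the matrix).
#' @param labels 0/1 labels aligned with the rows.
#' @return An object of class `pattern_distribution` with tibbles
#'   `pattern_probs` (`pattern`, `prob`), `joint_probs` (`pattern`, `y`,
#'   `prob`), `label_probs` (`y`, `prob`), plus `subset` and `n_samples`.
#' @export
empirical_joint <- function(fingerprints, bits, labels) {
  parts <- validate_fingerprints(fingerprints)
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(parts$compound_ids),
            all(labels %in% c(0L, 1L)))
  cols <- resolve_bits(parts, bits)
  n <- length(labels)
  pattern <- unname(apply(parts$matrix[, cols, drop = FALSE], 1L, paste,
                          collapse = ""))
  joint <- tibble::tibble(pattern = pattern, y = labels) |>
    dplyr::count(.data$pattern, .data$y, name = "count") |>
    dplyr::mutate(prob = .data$count / n) |>
    dplyr::select("pattern", "y", "prob") |>
    dplyr::arrange(.data$pattern, .data$y)
  marg <- joint |>
    dplyr::summarise(prob = sum(.data$prob), .by = "pattern") |>
    dplyr::arrange(.data$pattern)
  lab <- joint |>
    dplyr::summarise(prob = sum(.data$prob), .by = "y") |>
    dplyr::arrange(.data$y)
  structure(
    list(subset = as.integer(bits), pattern_probs = marg, joint_probs = joint,
         label_probs = lab, n_samples = n),
    class = "pattern_distribution"
  )
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> %d bits (%s), %d observed patterns, n = %d\n",
              length(x$subset), paste(x$subset, collapse = ","),
              nrow(x$pattern_probs), x$n_samples))
  invisible(x)
}

#' Normalized information content (AIC) of a bit group
#'
#' The score of a group of bits X with respect to a binary activity label Y
#' is the mutual information I(X; Y) of the empirical joint pattern/label
#' distribution, normalized by the Shannon entropy H(Y) of the label:
#' \deqn{AIC_y(X) = \frac{\sum_{x} \sum_{y} P(x;y) \log_2 \frac{P(x;y)}{P(x) P(y)}}{-\sum_y P(y) \log_2 P(y)}}
#' All logs are base 2 and 0 log 0 = 0. The score lies in \[0, 1\]: 0 when
#' the bit group is independent of the label, 1 when the observed patterns
#' determine the label exactly.
#'
#' @inheritParams empirical_joint
#' @return The AIC score, a number in \[0, 1\].
#' @export
#' @examples
#' fp <- tibble::tibble(compound_id = letters[1:4],
#'                      `0` = c(1L, 1L, 0L, 0L), `1` = c(1L, 0L, 1L, 0L))
#' aic_score(fp, 0, c(1, 1, 0, 0))  # bit identical to the label -> 1
#' aic_score(fp, 1, c(1, 1, 0, 0))  # independent bit -> 0
aic_score <- function(fingerprints, bits, labels) {
  parts <- validate_fingerprints(fingerprints)
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(parts$compound_ids),
            all(labels %in% c(0L, 1L)))
  check_two_classes(labels)
  cols <- resolve_bits(parts, bits)
  Hy <- entropy2(mean(labels == 1L))
  px <- pattern_index(parts$matrix, cols)
  nmi_from_pattern(px$pat, px$m, labels, Hy)
}

#' Brute-force AIC over the full pattern space (independent oracle)
#'
#' Computes the same quantity as [aic_score()] by explicitly enumerating all
#' 2^N patterns of the subset (absent patterns contribute nothing) and summing
#' the defining formula term by term. Exponential in the subset size, so it is
#' restricted to at most 16 bits; intended as a correctness oracle.
#'
#' @inheritParams empirical_joint
#' @return The AIC score in \[0, 1\].
#' @export
brute_force_aic <- function(fingerprints, bits, labels) {
  parts <- validate_fingerprints(fingerprints)
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(parts$compound_ids),
            all(labels %in% c(0L, 1L)))
  check_two_classes(labels)
  if (length(bits) > 16) stop("brute_force_aic is limited to 16 bits", call. = FALSE)
  cols <- resolve_bits(parts, bits)
  sub <- parts$matrix[, cols, drop = FALSE]
  n <- length(labels)
  N <- length(cols)
  # pattern id of each row: little-endian binary encoding, 1-based
  weights <- 2L^(seq_len(N) - 1L)
  row_id <- as.integer(sub %*% weights) + 1L
  py <- c(mean(labels == 0L), mean(labels == 1L))
  Hy <- -sum(py[py > 0] * log2(py[py > 0]))
  mi <- 0
  for (pid in seq_len(2L^N)) {
    in_pattern <- row_id == pid
    px <- mean(in_pattern)
    if (px == 0) next   # unobserved pattern: zero probability, zero contribution
    for (yv in c(0L, 1L)) {
      pxy <- mean(in_pattern & labels == yv)
      if (pxy == 0) next
      mi <- mi + pxy * log2(pxy / (px * py[yv + 1L]))
    }
  }
  mi / Hy
}

#' Average AIC of a bit group over several classification tasks
#'
#' The multi-target score is the unweighted arithmetic mean of the per-task
#' [aic_score()] values; per-task sample sizes do not weight the mean.
#'
#' @param tasks A [labeled_dataset()] or a list of them, sharing a bit
#'   universe.
#' @param bits Integer bit ids present in every task's matrix.
#' @param weights Optional per-task weights (default equal); normalized to
#'   sum to 1.
#' @return Mean AIC in \[0, 1\].
#' @export
aic_score_multi <- function(tasks, bits, weights = NULL) {
  tasks <- as_task_list(tasks)
  scores <- vapply(tasks, function(t) aic_score(t$fingerprints, bits, t$labels),
                   numeric(1))
  if (is.null(weights)) return(mean(scores))
  stopifnot(length(weights) == length(scores), all(weights >= 0), sum(weights) > 0)
  sum(scores * weights) / sum(weights)
}

as_task_list <- function(tasks) {
  if (inherits(tasks, "labeled_dataset")) tasks <- list(tasks)
  if (!is.list(tasks) || length(tasks) == 0 ||
      !all(vapply(tasks, inherits, logical(1), "labeled_dataset"))) {
    stop("tasks must be a labeled_dataset or a non-empty list of them",
         call. = FALSE)
  }
  tasks
}

#' Rank every bit individually by its singleton AIC
#'
#' Diagnostic baseline for the group selector: scores each bit on its own.
#' Ties are ordered by ascending bit id.
#'
#' @param dataset A [labeled_dataset()].
#' @return A tibble with columns `bit` and `aic`, sorted by descending `aic`
#'   then ascending `bit`.
#' @export
rank_bits_individual <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  parts <- validate_fingerprints(dataset$fingerprints)
  y <- dataset$labels
  check_two_classes(y, dataset$task_id)
  Hy <- entropy2(mean(y == 1L))
  scores <- vapply(seq_along(parts$bit_ids), function(j) {
    px <- densify(parts$matrix[, j] + 1L, 2L)
    nmi_from_pattern(px$pat, px$m, y, Hy)
  }, numeric(1))
  tibble::tibble(bit = parts$bit_ids, aic = scores) |>
    dplyr::arrange(dplyr::desc(.data$aic), .data$bit)
}

# ---- greedy selection --------------------------------------------------------

#' Greedy AIC-MAX bit selection
#'
#' Forward selection of a maximally informative bit subset: starting from the
#' empty set, each step adds the candidate bit whose addition maximizes the
#' (multi-task mean) AIC of the growing group. Ties are broken by higher
#' individual (singleton) AIC, then by lower bit id, which makes the run fully
#' deterministic — important because the empirical score saturates at 1.0 once
#' the observed patterns separate the classes, after which all candidates tie.
#' Selection stops after `min(k, number of bits)` steps.
#'
#' @param tasks A [labeled_dataset()] or list of them sharing a bit universe;
#'   with several tasks the maximized score is the unweighted mean over tasks.
#' @param k Number of bits to select (default 100).
#' @return An object of class `selection_result`: `task_ids`, `selected`
#'   (ordered bit ids), `trajectory` (AIC after each addition, non-decreasing),
#'   `saturated_at` (first step within 1e-9 of 1.0, or `NA`), and the
#'   parameters of the run.
#' @export
#' @examples
#' fp <- tibble::tibble(compound_id = letters[1:4],
#'                      `0` = c(1L, 1L, 0L, 0L), `1` = c(0L, 1L, 0L, 1L))
#' sel <- greedy_select(labeled_dataset(fp, c(1, 1, 0, 0)), k = 2)
#' sel$selected
greedy_select <- function(tasks, k = 100) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  tasks <- as_task_list(tasks)
  prep <- lapply(tasks, function(t) {
    parts <- validate_fingerprints(t$fingerprints)
    check_two_classes(t$labels, t$task_id)
    ord <- order(parts$bit_ids)
    list(mat = parts$matrix[, ord, drop = FALSE],
         bit_ids = parts$bit_ids[ord],
         y = t$labels,
         Hy = entropy2(mean(t$labels == 1L)))
  })
  bit_ids <- prep[[1]]$bit_ids
  if (length(bit_ids) == 0) stop("tasks have no bit columns", call. = FALSE)
  for (p in prep[-1]) {
    if (!identical(p$bit_ids, bit_ids)) {
      stop("all tasks must share the same bit universe", call. = FALSE)
    }
  }
  B <- length(bit_ids)
  n_steps <- min(k, B)

  # singleton scores (mean over tasks) for the tie-break rule
  singles <- rowMeans(vapply(prep, function(p) {
    vapply(seq_len(B), function(j) {
      dens <- densify(p$mat[, j] + 1L, 2L)
      nmi_from_pattern(dens$pat, dens$m, p$y, p$Hy)
    }, numeric(1))
  }, numeric(B)))

  state <- lapply(prep, function(p) list(pat = rep.int(1L, length(p$y)), m = 1L))
  remaining <- rep.int(TRUE, B)
  selected <- integer(n_steps)
  trajectory <- numeric(n_steps)

  for (step in seq_len(n_steps)) {
    cand <- which(remaining)
    scores <- vapply(cand, function(j) {
      mean(vapply(seq_along(prep), function(ti) {
        p <- prep[[ti]]
        s <- state[[ti]]
        key <- (s$pat - 1L) * 2L + p$mat[, j] + 1L
        nmi_from_pattern(key, 2L * s$m, p$y, p$Hy)
      }, numeric(1)))
    }, numeric(1))
    best <- max(scores)
    tied <- cand[scores >= best - 1e-12]
    if (length(tied) > 1) {
      top <- tied[singles[tied] >= max(singles[tied]) - 1e-12]
      pick <- top[which.min(bit_ids[top])]
    } else {
      pick <- tied
    }
    selected[step] <- bit_ids[pick]
    trajectory[step] <- scores[match(pick, cand)]
    remaining[pick] <- FALSE
    state <- lapply(seq_along(prep), function(ti) {
      p <- prep[[ti]]
      s <- state[[ti]]
      key <- (s$pat - 1L) * 2L + p$mat[, pick] + 1L
      densify(key, 2L * s$m)
    })
  }
  sat <- which(trajectory >= 1 - 1e-9)
  structure(
    list(task_ids = vapply(tasks, `[[`, character(1), "task_id"),
         selected = selected,
         trajectory = trajectory,
         saturated_at = if (length(sat) > 0) sat[1] else NA_integer_,
         k = k, n_bits_total = B),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d bit(s) selected for task(s) %s (k = %d, %d bits available)\n",
              length(x$selected), paste(x$task_ids, collapse = ", "),
              x$k, x$n_bits_total))
  cat(sprintf("  final AIC %.4f%s\n", x$trajectory[length(x$trajectory)],
              if (!is.na(x$saturated_at))
                sprintf(", saturated at step %d", x$saturated_at) else ""))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param x A `selection_result`.
#' @param path Output path.
#' @param parameters Optional named list of run parameters to embed.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path, parameters = list()) {
  stopifnot(inherits(x, "selection_result"))
  obj <- list(
    task_ids = x$task_ids,
    selected = x$selected,
    trajectory = x$trajectory,
    saturated_at = x$saturated_at,
    parameters = c(list(k = x$k), parameters),
    tool_version = as.character(utils::packageVersion("aicmax"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
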