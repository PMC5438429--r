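#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), in \[-1, 1\]:
#' +1 is perfect prediction, 0 a prediction independent of the truth, -1 a
#' perfectly inverted prediction. When any marginal factor is zero the
#' denominator vanishes and the conventional value 0 is returned with a
#' warning.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (at least one positive).
#' @return MCC in \[-1, 1\].
#' @export
#' @examples
#' mcc(tp = 5, fp = 0, tn = 5, fn = 0)   # 1
#' mcc(tp = 0, fp = 5, tn = 0, fn = 5)   # -1
mcc <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  # marginal products exceed integer range quickly; work in double throughout
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    warning("degenerate confusion matrix (a marginal is zero); returning MCC = 0",
            call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

mcc_from_predictions <- function(truth, pred) {
  mcc(tp = sum(truth == 1L & pred == 1L),
      fp = sum(truth == 0L & pred == 1L),
      tn = sum(truth == 0L & pred == 0L),
      fn = sum(truth == 1L & pred == 0L))
}

# ---- learner adapters --------------------------------------------------------

#' Create a classifier adapter
#'
#' The evaluation harness is classifier-agnostic: a learner is a pair of
#' functions, `fit(x, y, seed)` returning a model and `predict(model, x)`
#' returning 0/1 labels, where `x` is an integer 0/1 matrix with one column
#' per bit.
#'
#' @param name Learner name (recorded in reports).
#' @param fit Function `(x, y, seed) -> model`.
#' @param predict Function `(model, x) -> integer vector of 0/1`.
#' @return An object of class `fp_learner`.
#' @export
new_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "fp_learner")
}

#' Random-forest learner (default evaluation classifier)
#'
#' A ranger random forest with 500 trees and `floor(sqrt(p))` candidate
#' features per split, run single-threaded with a fixed seed so evaluations
#' are reproducible.
#'
#' @param num_trees Number of trees (default 500).
#' @param mtry Features per split; default `floor(sqrt(ncol(x)))`.
#' @return An `fp_learner`.
#' @export
learner_random_forest <- function(num_trees = 500, mtry = NULL) {
  new_learner(
    name = sprintf("random_forest(num_trees=%d)", num_trees),
    fit = function(x, y, seed) {
      colnames(x) <- paste0("b", seq_len(ncol(x)))
      ranger::ranger(
        x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
        num.trees = num_trees,
        mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry,
        seed = seed, num.threads = 1
      )
    },
    predict = function(model, x) {
      colnames(x) <- paste0("b", seq_len(ncol(x)))
      as.integer(as.character(
        stats::predict(model, data = as.data.frame(x), num.threads = 1)$predictions))
    }
  )
}

#' Deterministic decision-stump learner
#'
#' A trivial, fully deterministic classifier for testing the evaluation
#' harness: picks the single bit (and polarity) with the highest training
#' accuracy, falling back to the majority class when no bit beats it. Ties go
#' to the lower column index. Uses no randomness, so harness-level
#' reproducibility checks isolate the harness itself.
#'
#' @return An `fp_learner`.
#' @export
learner_stump <- function() {
  new_learner(
    name = "decision_stump",
    fit = function(x, y, seed) {
      maj <- as.integer(mean(y) >= 0.5)
      base_acc <- max(mean(y == 1L), mean(y == 0L))
      if (ncol(x) == 0) return(list(kind = "majority", class = maj))
      agree <- colMeans(x == y)
      acc <- pmax(agree, 1 - agree)
      j <- which.max(acc)   # first maximum: lower index wins ties
      if (acc[j] <= base_acc) {
        list(kind = "majority", class = maj)
      } else {
        list(kind = "stump", j = j, flip = agree[j] < 1 - agree[j])
      }
    },
    predict = function(model, x) {
      if (model$kind == "majority") return(rep.int(model$class, nrow(x)))
      v <- x[, model$j]
      if (model$flip) 1L - v else as.integer(v)
    }
  )
}

# ---- cross-validation --------------------------------------------------------

stratified_folds <- function(y, folds, seed) {
  withr::with_seed(seed, {
    f <- integer(length(y))
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(sample.int(folds), length(idx)))
    }
    f
  })
}

#' Cross-validated MCC of a (possibly reduced) representation
#'
#' Stratified k-fold cross-validation with a fixed seed: out-of-fold
#' predictions are pooled and the MCC is computed once on the pooled
#' confusion counts. `bits = NULL` uses the full matrix; otherwise columns
#' are restricted to `bits` before training.
#'
#' @param dataset A [labeled_dataset()].
#' @param bits Integer bit ids to restrict to, or `NULL` for all bits.
#' @param learner An `fp_learner` (default [learner_random_forest()]).
#' @param folds Number of CV folds (default 10); reduced with a warning when
#'   the smaller class has fewer members, hard error below 2.
#' @param seed Integer seed driving fold assignment and the learner.
#' @return Pooled out-of-fold MCC.
#' @export
cross_validated_mcc <- function(dataset, bits = NULL,
                                learner = learner_random_forest(),
                                folds = 10, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(learner, "fp_learner"))
  parts <- validate_fingerprints(dataset$fingerprints)
  y <- dataset$labels
  check_two_classes(y, dataset$task_id)
  x <- parts$matrix
  if (!is.null(bits)) {
    x <- x[, resolve_bits(parts, bits), drop = FALSE]
  }
  min_class <- min(sum(y == 1L), sum(y == 0L))
  if (min_class < folds) {
    if (min_class < 2) {
      stop("task `", dataset$task_id, "`: smaller class has ", min_class,
           " member(s); need at least 2 for cross-validation", call. = FALSE)
    }
    warning("task `", dataset$task_id, "`: reducing folds from ", folds,
            " to ", min_class, " (smaller class size)", call. = FALSE)
    folds <- min_class
  }
  fold <- stratified_folds(y, folds, seed)
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    test <- fold == f
    model <- learner$fit(x[!test, , drop = FALSE], y[!test], seed = seed + f)
    pred[test] <- learner$predict(model, x[test, , drop = FALSE])
  }
  mcc_from_predictions(y, pred)
}

# ---- Wilcoxon signed-rank test ----------------------------------------------

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; absolute differences are ranked with
#' average ranks for ties; the statistic is the sum of ranks of the positive
#' differences. For n <= 25 the one-sided p-value is exact — the null
#' distribution of the statistic is obtained from the generating function
#' over all 2^n sign assignments (a convolution over the ranks, so ties are
#' handled exactly). For larger n a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' @param diffs Numeric vector of paired differences (at least one nonzero).
#' @param alternative `"greater"` (default; positive shift), `"less"`, or
#'   `"two.sided"`.
#' @return A list with `statistic` (rank sum of positive differences), `p`,
#'   `n` (nonzero differences used) and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p   # 1/32
wilcoxon_signed_rank <- function(diffs,
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(diffs), !anyNA(diffs))
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; the signed-rank test is undefined",
                   call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact tail via the rank generating function; 2*rank is always integer
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    f <- numeric(S + 1)     # f[s + 1] = number of sign assignments with sum s
    f[1] <- 1
    for (v in r2) {
      g <- f
      g[(v + 1):(S + 1)] <- g[(v + 1):(S + 1)] + f[1:(S + 1 - v)]
      f <- g
    }
    total <- 2^n
    W2 <- as.integer(round(2 * W))
    p_ge <- sum(f[(W2 + 1):(S + 1)]) / total          # P(W >= w)
    p_le <- sum(f[1:(W2 + 1)]) / total                # P(W <= w)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- switch(alternative,
                greater = stats::pnorm((W - mu - 0.5) / sqrt(sigma2),
                                       lower.tail = FALSE),
                less = stats::pnorm((W - mu + 0.5) / sqrt(sigma2)),
                two.sided = min(1, 2 * stats::pnorm(
                  (abs(W - mu) - 0.5) / sqrt(sigma2), lower.tail = FALSE)))
    method <- "normal"
  }
  list(statistic = W, p = p, n = n, method = method)
}

# ---- raw vs reduced comparison ----------------------------------------------

#' Compare raw and reduced fingerprint representations across tasks
#'
#' For every task, computes the cross-validated MCC of the full bit matrix
#' (`mcc_raw`) and of the reduced bit subset (`mcc_reduced`), assigns a sign
#' (`+` when the reduced representation improves MCC by more than
#' `nc_tolerance`, `-` when it is worse by more than that, `nc` otherwise),
#' and runs a one-sided Wilcoxon signed-rank test (reduced >= raw) on the
#' non-nc paired differences.
#'
#' @param tasks List of [labeled_dataset()]s.
#' @param reduced_subsets Named list (by task id) of integer bit-id vectors,
#'   one per task.
#' @param learner An `fp_learner` (default [learner_random_forest()]).
#' @param folds CV folds (default 10).
#' @param seed Integer seed; task i uses `seed + i` so fold draws differ
#'   across tasks but the whole report is reproducible.
#' @param nc_tolerance Half-width of the "no change" band on the MCC
#'   difference (default 0.005).
#' @return An object of class `evaluation_report`: tibble `per_task`
#'   (`task_id`, `mcc_raw`, `mcc_reduced`, `delta`, `sign`), counts
#'   `n_improved` / `n_worse` / `n_nc`, `wilcoxon_statistic`, `wilcoxon_p`
#'   (`NA` when all tasks are nc and the test is skipped), and the run
#'   parameters.
#' @export
compare_representations <- function(tasks, reduced_subsets,
                                    learner = learner_random_forest(),
                                    folds = 10, seed = 1,
                                    nc_tolerance = 0.005) {
  tasks <- as_task_list(tasks)
  ids <- vapply(tasks, `[[`, character(1), "task_id")
  missing <- setdiff(ids, names(reduced_subsets))
  if (length(missing) > 0) {
    stop("no reduced subset for task(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_task <- purrr::map_dfr(seq_along(tasks), function(i) {
    t <- tasks[[i]]
    raw <- cross_validated_mcc(t, bits = NULL, learner = learner,
                               folds = folds, seed = seed + i)
    red <- cross_validated_mcc(t, bits = reduced_subsets[[t$task_id]],
                               learner = learner, folds = folds,
                               seed = seed + i)
    tibble::tibble(task_id = t$task_id, mcc_raw = raw, mcc_reduced = red,
                   delta = red - raw)
  })
  per_task$sign <- dplyr::case_when(
    per_task$delta > nc_tolerance ~ "+",
    per_task$delta < -nc_tolerance ~ "-",
    TRUE ~ "nc"
  )
  nonzero <- per_task$delta[per_task$sign != "nc"]
  if (length(nonzero) == 0) {
    wil <- list(statistic = NA_real_, p = NA_real_, n = 0L, method = "skipped")
  } else {
    wil <- wilcoxon_signed_rank(nonzero, alternative = "greater")
  }
  structure(
    list(per_task = per_task,
         n_improved = sum(per_task$sign == "+"),
         n_worse = sum(per_task$sign == "-"),
         n_nc = sum(per_task$sign == "nc"),
         wilcoxon_statistic = wil$statistic,
         wilcoxon_p = wil$p,
         wilcoxon_method = wil$method,
         parameters = list(learner = learner$name, folds = folds, seed = seed,
                           nc_tolerance = nc_tolerance,
                           alternative = "greater",
                           protocol = "stratified CV, pooled out-of-fold MCC")),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d tasks: %d improved (+), %d worse (-), %d nc\n",
              nrow(x$per_task), x$n_improved, x$n_worse, x$n_nc))
  if (x$wilcoxon_method == "skipped") {
    cat("  Wilcoxon signed-rank: skipped (no non-nc differences)\n")
  } else {
    cat(sprintf("  Wilcoxon signed-rank (reduced >= raw, %s): W = %g, p = %.4g\n",
                x$wilcoxon_method, x$wilcoxon_statistic, x$wilcoxon_p))
  }
  invisible(x)
}

#' Write an evaluation report to JSON and TSV
#'
#' @param x An `evaluation_report`.
#' @param json_path Path for the full JSON report (or `NULL` to skip).
#' @param tsv_path Path for the per-task +/-/nc TSV table (or `NULL`).
#' @return `x`, invisibly.
#' @export
write_evaluation_report <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "evaluation_report"))
  if (!is.null(json_path)) {
    obj <- list(per_task = x$per_task,
                n_improved = x$n_improved, n_worse = x$n_worse, n_nc = x$n_nc,
                wilcoxon_statistic = x$wilcoxon_statistic,
                wilcoxon_p = x$wilcoxon_p,
                wilcoxon_method = x$wilcoxon_method,
                parameters = x$parameters,
                tool_version = as.character(utils::packageVersion("aicmax")))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(x$per_task, tsv_path, progress = FALSE)
  }
  invisible(x)
}
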