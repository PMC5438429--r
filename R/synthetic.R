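#' Specification for a synthetic fingerprint dataset
#'
#' Describes a binary fingerprint dataset with known ground truth: planted
#' bits whose occurrence probability differs between actives and inactives,
#' XOR pairs that are jointly (but not individually) informative, exact
#' duplicate bits, and pure-noise bits independent of the label. Every other
#' module is testable against datasets generated from such a spec.
#'
#' @param n_active,n_inactive Compounds per class, per target.
#' @param planted_bits Data frame with columns `bit`, `p_active`,
#'   `p_inactive`: bit is 1 with probability `p_active` given label 1 and
#'   `p_inactive` given label 0.
#' @param xor_pairs List of length-2 integer vectors; the bits of a pair are
#'   drawn uniformly and the label of the pair's designated rows is then set
#'   to their parity. Rows are split evenly across pairs.
#' @param duplicates Data frame with columns `bit`, `source`: `bit` copies
#'   `source` exactly.
#' @param n_noise_bits Number of label-independent noise bits, each 1 with
#'   probability `p_noise`; ids are assigned after the largest declared id.
#' @param p_noise Occurrence probability of noise bits (default 0.1).
#' @param n_targets Number of replicate tasks to generate (default 1).
#' @param seed Integer seed; one global seed drives a hierarchical
#'   per-target, per-bit stream, so adding bits does not perturb existing
#'   columns.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active, n_inactive,
                           planted_bits = NULL, xor_pairs = NULL,
                           duplicates = NULL, n_noise_bits = 0,
                           p_noise = 0.1, n_targets = 1, seed = 1) {
  stopifnot(n_active >= 1, n_inactive >= 1, n_noise_bits >= 0,
            p_noise >= 0, p_noise <= 1, n_targets >= 1)
  if (is.null(planted_bits)) {
    planted_bits <- tibble::tibble(bit = integer(0), p_active = numeric(0),
                                   p_inactive = numeric(0))
  }
  stopifnot(all(c("bit", "p_active", "p_inactive") %in% names(planted_bits)),
            all(planted_bits$p_active >= 0 & planted_bits$p_active <= 1),
            all(planted_bits$p_inactive >= 0 & planted_bits$p_inactive <= 1))
  xor_pairs <- xor_pairs %||% list()
  stopifnot(all(vapply(xor_pairs, length, integer(1)) == 2))
  xor_bits <- as.integer(unlist(xor_pairs))
  if (is.null(duplicates)) {
    duplicates <- tibble::tibble(bit = integer(0), source = integer(0))
  }
  stopifnot(all(c("bit", "source") %in% names(duplicates)))
  declared <- c(planted_bits$bit, xor_bits, duplicates$bit)
  if (anyDuplicated(declared)) {
    stop("bit ids must be unique across roles (planted / xor / duplicate); ",
         "duplicated: ", paste(unique(declared[duplicated(declared)]),
                               collapse = ", "), call. = FALSE)
  }
  src_universe <- c(planted_bits$bit, xor_bits)
  if (!all(duplicates$source %in% src_universe)) {
    stop("duplicate sources must be planted or xor bits", call. = FALSE)
  }
  noise_ids <- if (n_noise_bits > 0) {
    start <- if (length(declared) > 0) max(declared) + 1L else 0L
    seq.int(start, length.out = n_noise_bits)
  } else integer(0)
  structure(
    list(n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
         planted_bits = tibble::as_tibble(planted_bits), xor_pairs = xor_pairs,
         duplicates = tibble::as_tibble(duplicates),
         noise_ids = noise_ids, p_noise = p_noise,
         n_targets = as.integer(n_targets), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sub_seed <- function(seed, t, bit) {
  as.integer((as.double(seed) + 1000003 * t + 7919 * (bit + 1)) %% 2147483629)
}

#' Closed-form singleton AIC of a planted bit
#'
#' Normalized mutual information of the 2x2 distribution in which the bit is
#' 1 with probability `p_active` among actives and `p_inactive` among
#' inactives, and the label is 1 with probability `prev`.
#'
#' @param p_active,p_inactive Conditional occurrence probabilities.
#' @param prev Prevalence P(y = 1).
#' @return The population AIC in \[0, 1\].
#' @export
closed_form_aic <- function(p_active, p_inactive, prev = 0.5) {
  stopifnot(prev > 0, prev < 1)
  joint <- c(prev * p_active, prev * (1 - p_active),
             (1 - prev) * p_inactive, (1 - prev) * (1 - p_inactive))
  px <- c(joint[1] + joint[3], joint[2] + joint[4])     # P(x=1), P(x=0)
  py <- c(prev, 1 - prev)
  marg <- c(px[1] * py[1], px[2] * py[1], px[1] * py[2], px[2] * py[2])
  pos <- joint > 0
  mi <- sum(joint[pos] * log2(joint[pos] / marg[pos]))
  mi / entropy2(prev)
}

#' Generate synthetic labeled datasets from a spec
#'
#' Labels are laid out first (`n_active` ones then `n_inactive` zeros);
#' planted bits are drawn conditional on the class; XOR-pair bits are drawn
#' uniformly and the label of their designated rows is then overridden to
#' the pair's parity; duplicates copy their source column exactly; noise
#' bits are independent of the label. Fully reproducible from the spec seed.
#' The manifest records every bit's role and, for planted bits, the
#' closed-form singleton AIC (exact when no XOR override rewrites labels).
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_data`: `tasks` (list of
#'   [labeled_dataset()], task ids `T1`, `T2`, ...), `manifest` (tibble with
#'   columns `bit`, `role`, `p_active`, `p_inactive`, `source`,
#'   `aic_closed_form`) and the `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_active + spec$n_inactive
  prev <- spec$n_active / n
  all_bits <- sort(c(spec$planted_bits$bit, unlist(spec$xor_pairs),
                     spec$duplicates$bit, spec$noise_ids))
  tasks <- vector("list", spec$n_targets)
  for (t in seq_len(spec$n_targets)) {
    y <- c(rep.int(1L, spec$n_active), rep.int(0L, spec$n_inactive))
    cols <- list()
    for (i in seq_len(nrow(spec$planted_bits))) {
      b <- spec$planted_bits$bit[i]
      p <- ifelse(y == 1L, spec$planted_bits$p_active[i],
                  spec$planted_bits$p_inactive[i])
      cols[[as.character(b)]] <- withr::with_seed(
        sub_seed(spec$seed, t, b), stats::rbinom(n, 1L, p))
    }
    if (length(spec$xor_pairs) > 0) {
      blocks <- split(seq_len(n),
                      rep(seq_along(spec$xor_pairs), length.out = n))
      for (pi in seq_along(spec$xor_pairs)) {
        pair <- spec$xor_pairs[[pi]]
        v1 <- withr::with_seed(sub_seed(spec$seed, t, pair[1]),
                               stats::rbinom(n, 1L, 0.5))
        v2 <- withr::with_seed(sub_seed(spec$seed, t, pair[2]),
                               stats::rbinom(n, 1L, 0.5))
        cols[[as.character(pair[1])]] <- v1
        cols[[as.character(pair[2])]] <- v2
        rows <- blocks[[pi]]
        y[rows] <- as.integer(xor(v1[rows] == 1L, v2[rows] == 1L))
      }
    }
    for (i in seq_len(nrow(spec$duplicates))) {
      cols[[as.character(spec$duplicates$bit[i])]] <-
        cols[[as.character(spec$duplicates$source[i])]]
    }
    for (b in spec$noise_ids) {
      cols[[as.character(b)]] <- withr::with_seed(
        sub_seed(spec$seed, t, b), stats::rbinom(n, 1L, spec$p_noise))
    }
    mat <- do.call(cbind, cols[as.character(all_bits)])
    tasks[[t]] <- labeled_dataset(
      fingerprint_tibble(mat, sprintf("T%d_c%05d", t, seq_len(n)), all_bits),
      y, task_id = paste0("T", t))
  }
  planted_aic <- vapply(seq_len(nrow(spec$planted_bits)), function(i) {
    closed_form_aic(spec$planted_bits$p_active[i],
                    spec$planted_bits$p_inactive[i], prev)
  }, numeric(1))
  dup_src <- spec$duplicates$source
  manifest <- dplyr::bind_rows(
    tibble::tibble(bit = spec$planted_bits$bit, role = "planted",
                   p_active = spec$planted_bits$p_active,
                   p_inactive = spec$planted_bits$p_inactive,
                   source = NA_integer_, aic_closed_form = planted_aic),
    tibble::tibble(bit = as.integer(unlist(spec$xor_pairs)), role = "xor",
                   p_active = 0.5, p_inactive = 0.5, source = NA_integer_,
                   aic_closed_form = 0),
    tibble::tibble(bit = spec$duplicates$bit, role = "duplicate",
                   p_active = NA_real_, p_inactive = NA_real_,
                   source = as.integer(dup_src),
                   aic_closed_form = NA_real_),
    tibble::tibble(bit = spec$noise_ids, role = "noise",
                   p_active = spec$p_noise, p_inactive = spec$p_noise,
                   source = NA_integer_, aic_closed_form = 0)
  ) |> dplyr::arrange(.data$bit)
  # a duplicate inherits its source's closed-form score
  if (nrow(spec$duplicates) > 0) {
    src_aic <- manifest$aic_closed_form[match(manifest$source, manifest$bit)]
    manifest$aic_closed_form[manifest$role == "duplicate"] <-
      src_aic[manifest$role == "duplicate"]
  }
  structure(list(tasks = tasks, manifest = manifest, spec = spec),
            class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat(sprintf("<synthetic_data> %d task(s), %d bits (%s)\n",
              length(x$tasks), nrow(x$manifest),
              paste(sprintf("%d %s", table(x$manifest$role),
                            names(table(x$manifest$role))), collapse = ", ")))
  invisible(x)
}

#' Generate a multi-target suite for pairwise selectivity analysis
#'
#' Each target gets its own pool of active compounds and a set of
#' characteristic planted bits that occur with probability `p_hi` among its
#' own actives and `p_lo` among every other target's actives, so every
#' target pair differs on the union of the two targets' characteristic bits
#' (effect size `p_hi - p_lo`). Noise bits are shared across targets.
#' Optionally injects dual-active compounds at a fixed per-target rate and
#' can nest one target's actives inside another's to create a degenerate
#' pair.
#'
#' @param n_targets Number of targets (>= 2).
#' @param n_per_target Active compounds per target (default 300).
#' @param bits_per_target Characteristic bits per target (default 1).
#' @param n_noise_bits Shared noise bits (default 40).
#' @param p_hi,p_lo Occurrence probabilities of a characteristic bit among
#'   its own target's actives versus other targets' actives (defaults 0.7
#'   and 0.1).
#' @param p_noise Noise-bit occurrence probability (default 0.15).
#' @param overlap_rate Fraction of each target's actives also made active at
#'   the next target (default 0), producing dual actives that pair tasks
#'   exclude.
#' @param nested_pair Optional integer pair `c(i, j)`: all but one of target
#'   i's actives are also made active at target j, so the (i, j) pair task is
#'   degenerate.
#' @param seed Integer seed.
#' @return A list with `actives` (tibble `target_id`, `compound_id`),
#'   `fingerprints` (one row per unique compound) and `manifest` (list with
#'   `per_target` characteristic-bit table, per-`pairs` discriminative bits,
#'   and the planted overlap counts).
#' @export
generate_pairwise_suite <- function(n_targets, n_per_target = 300,
                                    bits_per_target = 1, n_noise_bits = 40,
                                    p_hi = 0.7, p_lo = 0.1, p_noise = 0.15,
                                    overlap_rate = 0, nested_pair = NULL,
                                    seed = 1) {
  stopifnot(n_targets >= 2, n_per_target >= 2, bits_per_target >= 1,
            p_hi >= 0, p_hi <= 1, p_lo >= 0, p_lo <= 1,
            overlap_rate >= 0, overlap_rate < 1)
  targets <- sprintf("T%02d", seq_len(n_targets))
  char_bits <- lapply(seq_len(n_targets), function(t) {
    seq.int((t - 1L) * bits_per_target, length.out = bits_per_target)
  })
  noise_ids <- seq.int(n_targets * bits_per_target, length.out = n_noise_bits)
  all_bits <- c(unlist(char_bits), noise_ids)

  compounds <- tibble::tibble(
    compound_id = as.vector(vapply(seq_len(n_targets), function(t) {
      sprintf("%s_c%04d", targets[t], seq_len(n_per_target))
    }, character(n_per_target))),
    primary = rep(seq_len(n_targets), each = n_per_target)
  )
  n_cmp <- nrow(compounds)

  actives <- tibble::tibble(target_id = targets[compounds$primary],
                            compound_id = compounds$compound_id)
  n_overlap <- round(overlap_rate * n_per_target)
  if (n_overlap > 0) {
    extra <- purrr::map_dfr(seq_len(n_targets), function(t) {
      nxt <- targets[t %% n_targets + 1L]
      own <- compounds$compound_id[compounds$primary == t][seq_len(n_overlap)]
      tibble::tibble(target_id = nxt, compound_id = own)
    })
    actives <- dplyr::bind_rows(actives, extra) |> dplyr::distinct()
  }
  if (!is.null(nested_pair)) {
    stopifnot(length(nested_pair) == 2, all(nested_pair %in% seq_len(n_targets)),
              nested_pair[1] != nested_pair[2])
    own <- compounds$compound_id[compounds$primary == nested_pair[1]]
    actives <- dplyr::bind_rows(
      actives,
      tibble::tibble(target_id = targets[nested_pair[2]],
                     compound_id = own[-length(own)])) |>
      dplyr::distinct()
  }

  cols <- list()
  for (t in seq_len(n_targets)) {
    for (b in char_bits[[t]]) {
      p <- ifelse(compounds$primary == t, p_hi, p_lo)
      cols[[as.character(b)]] <- withr::with_seed(
        sub_seed(seed, 0L, b), stats::rbinom(n_cmp, 1L, p))
    }
  }
  for (b in noise_ids) {
    cols[[as.character(b)]] <- withr::with_seed(
      sub_seed(seed, 0L, b), stats::rbinom(n_cmp, 1L, p_noise))
  }
  mat <- do.call(cbind, cols[as.character(sort(all_bits))])
  fingerprints <- fingerprint_tibble(mat, compounds$compound_id, sort(all_bits))

  combos <- utils::combn(seq_len(n_targets), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    tibble::tibble(target_a = targets[a], target_b = targets[b],
                   discriminative_bits = list(sort(c(char_bits[[a]],
                                                     char_bits[[b]]))))
  })
  manifest <- list(
    per_target = tibble::tibble(
      target_id = rep(targets, each = bits_per_target),
      bit = unlist(char_bits)),
    pairs = pairs,
    noise_bits = noise_ids,
    overlap_per_target = n_overlap,
    effect = p_hi - p_lo
  )
  list(actives = actives, fingerprints = fingerprints, manifest = manifest,
       parameters = list(n_targets = n_targets, n_per_target = n_per_target,
                         bits_per_target = bits_per_target,
                         n_noise_bits = n_noise_bits, p_hi = p_hi,
                         p_lo = p_lo, p_noise = p_noise,
                         overlap_rate = overlap_rate, seed = seed))
}

#' Exactly balanced XOR dataset
#'
#' A deterministic dataset showcasing joint (non-additive) information: the
#' label is the parity of bits 0 and 1, all four (x1, x2) patterns occur
#' equally often, and every noise bit is exactly balanced within every
#' (x1, x2) cell. By construction every singleton AIC is exactly 0 while the
#' pair {0, 1} attains AIC 1, so greedy selection must rely on its
#' deterministic tie-break at the first step and on the group score at the
#' second.
#'
#' @param n_noise Number of noise bits (default 8; at most `reps`).
#' @param reps Replicates per (x1, x2) cell (default 8, giving 32 rows).
#' @return A [labeled_dataset()] with bits 0 (x1), 1 (x2) and noise bits
#'   2, 3, ....
#' @export
xor_showcase_dataset <- function(n_noise = 8, reps = 8) {
  stopifnot(reps >= 2, reps %% 2 == 0, n_noise >= 0, n_noise <= reps)
  grid <- expand.grid(r = seq_len(reps) - 1L, x2 = 0:1, x1 = 0:1)
  x1 <- grid$x1
  x2 <- grid$x2
  y <- as.integer(xor(x1 == 1L, x2 == 1L))
  cols <- list(`0` = as.integer(x1), `1` = as.integer(x2))
  for (j in seq_len(n_noise)) {
    # cyclic half-block shifts: balanced within every cell, all distinct
    cols[[as.character(j + 1L)]] <-
      as.integer(((grid$r + j - 1L) %% reps) < reps / 2)
  }
  mat <- do.call(cbind, cols)
  labeled_dataset(
    fingerprint_tibble(mat, sprintf("c%03d", seq_len(nrow(grid))),
                       seq_len(ncol(mat)) - 1L),
    y, task_id = "xor_showcase")
}

#' Write a synthetic dataset to disk
#'
#' Fingerprint matrices go to per-task CSV (the format [read_bit_matrix()]
#' reads), labels to per-task CSV, and the ground-truth manifest to JSON.
#'
#' @param x A `synthetic_data` object from [generate()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in x$tasks) {
    write_bit_matrix(t$fingerprints,
                     file.path(dir, sprintf("%s_fingerprints.csv", t$task_id)))
    readr::write_csv(tibble::tibble(compound_id = t$fingerprints$compound_id,
                                    label = t$labels),
                     file.path(dir, sprintf("%s_labels.csv", t$task_id)),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(manifest = x$manifest,
         spec = list(n_active = x$spec$n_active, n_inactive = x$spec$n_inactive,
                     p_noise = x$spec$p_noise, n_targets = x$spec$n_targets,
                     seed = x$spec$seed),
         tool_version = as.character(utils::packageVersion("aicmax"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
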