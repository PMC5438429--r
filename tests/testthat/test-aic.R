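test_that("label entropy matches closed forms", {
  expect_identical(label_entropy(c(1, 0, 1, 0)), 1)
  expect_identical(label_entropy(c(1, 1, 1)), 0)
  # P(y = 1) = 1/4: -(1/4) log2(1/4) - (3/4) log2(3/4)
  expect_equal(label_entropy(c(1, 0, 0, 0)), 0.811278124459133, tolerance = 1e-12)
  expect_error(label_entropy(integer(0)), "non-empty")
})

test_that("empirical_joint reproduces hand-counted probabilities", {
  fp <- tibble::tibble(compound_id = paste0("c", 1:8),
                       `0` = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pd <- empirical_joint(fp, 0, y)
  expect_s3_class(pd, "pattern_distribution")
  jp <- function(pat, yv) pd$joint_probs$prob[pd$joint_probs$pattern == pat &
                                              pd$joint_probs$y == yv]
  expect_equal(pd$pattern_probs$prob[pd$pattern_probs$pattern == "1"], 3 / 8)
  expect_equal(jp("1", 1), 3 / 8)
  expect_equal(jp("0", 1), 1 / 8)
  expect_equal(jp("0", 0), 4 / 8)
})

test_that("empirical_joint probabilities are consistent distributions", {
  fp <- random_fingerprints(60, 6, seed = 9)
  y <- random_labels(60, seed = 10)
  pd <- empirical_joint(fp, c(0, 3, 5), y)
  expect_equal(sum(pd$pattern_probs$prob), 1, tolerance = 1e-12)
  expect_equal(sum(pd$label_probs$prob), 1, tolerance = 1e-12)
  expect_equal(sum(pd$joint_probs$prob), 1, tolerance = 1e-12)
  # marginal consistency
  m1 <- pd$joint_probs |>
    dplyr::summarise(prob = sum(prob), .by = pattern) |>
    dplyr::arrange(pattern)
  expect_equal(m1$prob, pd$pattern_probs$prob, tolerance = 1e-12)
  m2 <- pd$joint_probs |>
    dplyr::summarise(prob = sum(prob), .by = y) |>
    dplyr::arrange(y)
  expect_equal(m2$prob, pd$label_probs$prob, tolerance = 1e-12)
  # only observed patterns appear
  expect_lte(nrow(pd$pattern_probs), min(2^3, 60))
  expect_true(all(pd$pattern_probs$prob > 0))
})

test_that("a one-bit perfect copy of the label has exactly two support points", {
  y <- c(1, 1, 0, 0, 1, 0)
  fp <- tibble::tibble(compound_id = paste0("c", 1:6), `4` = as.integer(y))
  pd <- empirical_joint(fp, 4, y)
  expect_identical(nrow(pd$joint_probs), 2L)
  expect_equal(pd$joint_probs$prob[pd$joint_probs$pattern == "1"], mean(y == 1))
})

test_that("constant bits give a single pattern with probability one", {
  fp <- tibble::tibble(compound_id = paste0("c", 1:5),
                       `0` = rep(0L, 5), `1` = rep(0L, 5))
  pd <- empirical_joint(fp, c(0, 1), c(1, 0, 1, 0, 1))
  expect_identical(pd$pattern_probs$pattern, "00")
  expect_equal(pd$pattern_probs$prob, 1)
})

test_that("aic_score hits the analytic anchor cases", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fp <- tibble::tibble(compound_id = paste0("c", 1:8),
                       perfect = as.integer(y),
                       indep = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
                       lumpy = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  names(fp) <- c("compound_id", "0", "1", "2")
  expect_identical(aic_score(fp, 0, y), 1)
  expect_identical(aic_score(fp, 1, y), 0)
  # hand count: MI = 3/8 + 1/8 log2(2/5) + 1/2 log2(8/5), H(Y) = 1
  expect_equal(aic_score(fp, 2, y),
               3 / 8 + 1 / 8 * log2(2 / 5) + 1 / 2 * log2(8 / 5),
               tolerance = 1e-12)
  expect_equal(aic_score(fp, 2, y), 0.548795, tolerance = 1e-6)
})

test_that("aic_score equals the brute-force oracle on random subsets", {
  for (trial in 1:25) {
    fp <- random_fingerprints(50, 12, seed = 100 + trial)
    y <- random_labels(50, seed = 200 + trial)
    sizes <- withr::with_seed(300 + trial, sample(1:8, 8, replace = TRUE))
    for (s in sizes) {
      bits <- withr::with_seed(400 + trial + s, sample(0:11, s))
      expect_equal(aic_score(fp, bits, y), brute_force_aic(fp, bits, y),
                   tolerance = 1e-10)
    }
  }
})

test_that("aic_score respects its algebraic invariances", {
  fp <- random_fingerprints(80, 10, seed = 5)
  y <- random_labels(80, seed = 6)
  bits <- c(2, 7, 4)
  s <- aic_score(fp, bits, y)
  expect_gte(s, 0)
  expect_lte(s, 1)
  # label symmetry
  expect_equal(aic_score(fp, bits, 1 - y), s, tolerance = 1e-12)
  # bit-order invariance
  expect_equal(aic_score(fp, c(4, 2, 7), y), s, tolerance = 1e-12)
  # duplication invariance: re-adding a selected bit never changes the score
  expect_equal(aic_score(fp, c(2, 7, 4, 7), y), s, tolerance = 1e-12)
})

test_that("adding any bit never decreases the empirical score", {
  fp <- random_fingerprints(40, 8, seed = 11)
  y <- random_labels(40, seed = 12)
  base_bits <- c(1, 5)
  base <- aic_score(fp, base_bits, y)
  for (b in setdiff(0:7, base_bits)) {
    expect_gte(aic_score(fp, c(base_bits, b), y), base - 1e-12)
  }
})

test_that("degenerate single-class tasks are rejected loudly", {
  fp <- random_fingerprints(10, 3)
  expect_error(aic_score(fp, 0, rep(1, 10)), "degenerate")
  expect_error(brute_force_aic(fp, 0, rep(0, 10)), "degenerate")
  expect_error(aic_score(fp, integer(0), random_labels(10)), "non-empty")
  expect_error(aic_score(fp, 99, random_labels(10)), "not present")
  expect_error(brute_force_aic(fp, rep(0:2, 6), random_labels(10)), "16 bits")
})

test_that("multi-task scores are the unweighted mean of per-task scores", {
  fp1 <- random_fingerprints(30, 5, seed = 21)
  fp2 <- random_fingerprints(40, 5, seed = 22)
  fp3 <- random_fingerprints(50, 5, seed = 23)
  tasks <- list(labeled_dataset(fp1, random_labels(30, seed = 31), "t1"),
                labeled_dataset(fp2, random_labels(40, seed = 32), "t2"),
                labeled_dataset(fp3, random_labels(50, seed = 33), "t3"))
  bits <- c(0, 2)
  per_task <- vapply(tasks, function(t) aic_score(t$fingerprints, bits, t$labels),
                     numeric(1))
  expect_equal(aic_score_multi(tasks, bits), mean(per_task), tolerance = 1e-12)
  # single task reduces to aic_score
  expect_identical(aic_score_multi(tasks[[1]], bits), per_task[1])
  # perfect + independent -> 0.5
  y <- c(1, 1, 0, 0)
  fpA <- tibble::tibble(compound_id = paste0("a", 1:4), `0` = as.integer(y))
  fpB <- tibble::tibble(compound_id = paste0("b", 1:4), `0` = c(1L, 0L, 1L, 0L))
  expect_equal(aic_score_multi(list(labeled_dataset(fpA, y, "A"),
                                    labeled_dataset(fpB, y, "B")), 0), 0.5)
  expect_error(aic_score_multi(tasks, 99), "not present")
})

test_that("individual ranking orders by score with ascending-id tie-break", {
  y <- c(1, 1, 1, 0, 0, 0)
  fp <- tibble::tibble(compound_id = paste0("c", 1:6),
                       `3` = as.integer(y), `1` = rep(0L, 6), `0` = rep(0L, 6))
  rk <- rank_bits_individual(labeled_dataset(fp, y))
  expect_identical(rk$bit[1], 3L)
  expect_identical(rk$aic[1], 1)
  expect_identical(rk$bit[-1], c(0L, 1L))   # constant bits tie at 0, id order
  expect_identical(rk$aic[-1], c(0, 0))
  # singleton ranking agrees with the direct 2x2 oracle
  fp2 <- random_fingerprints(100, 4, seed = 77)
  y2 <- random_labels(100, seed = 78)
  rk2 <- rank_bits_individual(labeled_dataset(fp2, y2))
  for (i in seq_len(nrow(rk2))) {
    col <- fp2[[as.character(rk2$bit[i])]]
    expect_equal(rk2$aic[i], singleton_aic_oracle(col, y2), tolerance = 1e-9)
  }
})

test_that("greedy selection exhausts the bit pool when k is large", {
  fp <- random_fingerprints(30, 6, seed = 41)
  y <- random_labels(30, seed = 42)
  sel <- greedy_select(labeled_dataset(fp, y), k = 50)
  expect_identical(sort(sel$selected), 0:5)
  expect_identical(length(sel$trajectory), 6L)
  expect_true(all(diff(sel$trajectory) >= -1e-12))
  expect_true(all(sel$trajectory >= 0 & sel$trajectory <= 1))
})

test_that("greedy selection recovers a jointly-informative XOR pair exactly", {
  ds <- xor_showcase_dataset()
  # every singleton is exactly uninformative by construction
  rk <- rank_bits_individual(ds)
  expect_true(all(rk$aic == 0))
  # exhaustive oracle: {0, 1} is the unique 2-subset attaining AIC 1
  bits <- as.integer(names(ds$fingerprints)[-1])
  combos <- utils::combn(bits, 2)
  scores <- apply(combos, 2L, function(b)
    brute_force_aic(ds$fingerprints, b, ds$labels))
  winners <- combos[, scores >= 1 - 1e-12, drop = FALSE]
  expect_identical(ncol(winners), 1L)
  expect_identical(sort(winners[, 1]), c(0L, 1L))
  # greedy finds it: bit 0 first by the id tie-break, then bit 1
  sel <- greedy_select(ds, k = 2)
  expect_identical(sel$selected, c(0L, 1L))
  expect_identical(sel$trajectory[2], 1)
  expect_identical(sel$saturated_at, 2L)
})

test_that("after saturation, selection falls through to the tie-break rule", {
  y <- c(1, 1, 0, 0)
  fp <- tibble::tibble(compound_id = paste0("c", 1:4),
                       `0` = as.integer(y),
                       `1` = c(0L, 1L, 0L, 1L),
                       `2` = c(1L, 0L, 1L, 0L))
  sel <- greedy_select(labeled_dataset(fp, y), k = 3)
  expect_identical(sel$selected[1], 0L)
  expect_identical(sel$saturated_at, 1L)
  expect_true(all(sel$trajectory == 1))
  # post-saturation candidates tie at 1.0 -> lower id first
  expect_identical(sel$selected, c(0L, 1L, 2L))
})

test_that("greedy contract errors fire", {
  fp <- random_fingerprints(10, 3)
  ds <- labeled_dataset(fp, random_labels(10))
  expect_error(greedy_select(ds, k = 0), "positive")
  expect_error(greedy_select(list(ds, labeled_dataset(fp, rep(1, 10))), k = 1),
               "degenerate")
  other <- labeled_dataset(random_fingerprints(10, 4), random_labels(10))
  expect_error(greedy_select(list(ds, other), k = 1), "bit universe")
})

test_that("selection results serialize to JSON and tidy into tables", {
  ds <- xor_showcase_dataset()
  sel <- greedy_select(ds, k = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(as.integer(back$selected), sel$selected)
  expect_equal(back$trajectory, sel$trajectory)
  td <- tidy(sel)
  expect_identical(td$bit, sel$selected)
  expect_identical(td$step, 1:3)
  g <- glance(sel)
  expect_identical(g$n_selected, 3L)
  expect_identical(g$final_aic, 1)
})
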