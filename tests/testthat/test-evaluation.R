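test_that("MCC matches its boundary anchors and the phi-coefficient oracle", {
  expect_identical(mcc(tp = 5, fp = 0, tn = 5, fn = 0), 1)
  expect_identical(mcc(tp = 0, fp = 5, tn = 0, fn = 5), -1)
  # prediction independent of truth: tp*tn == fp*fn
  expect_identical(mcc(tp = 30, fp = 20, tn = 20, fn = 30), 0)
  # direct formula evaluation, cross-checked against cor() on expanded vectors
  expect_equal(mcc(tp = 6, fp = 2, tn = 3, fn = 1),
               mcc_phi_oracle(tp = 6, fp = 2, tn = 3, fn = 1),
               tolerance = 1e-12)
  expect_equal(mcc(tp = 6, fp = 2, tn = 3, fn = 1), 16 / sqrt(1120),
               tolerance = 1e-12)
})

test_that("MCC symmetry properties hold on random confusion tables", {
  withr::with_seed(31, {
    for (i in 1:20) {
      cts <- as.list(rpois(4, 20) + 1)
      names(cts) <- c("tp", "fp", "tn", "fn")
      m <- do.call(mcc, cts)
      expect_gte(m, -1); expect_lte(m, 1)
      # swapping the positive/negative roles leaves MCC unchanged
      expect_equal(do.call(mcc, unname(cts[c("tn", "fn", "tp", "fp")])), m)
      # negating predictions negates MCC
      expect_equal(do.call(mcc, unname(cts[c("fn", "tn", "fp", "tp")])), -m)
    }
  })
})

test_that("degenerate confusion matrices return 0 with a warning", {
  expect_warning(z <- mcc(tp = 3, fp = 0, tn = 0, fn = 2), "degenerate")
  expect_identical(z, 0)
  expect_error(mcc(0, 0, 0, 0), "all confusion counts are zero")
})

test_that("the exact signed-rank tail equals literal sign enumeration", {
  cases <- list(c(1, 2, 3, 4, 5),
                c(1, -1, 2, -2),
                c(0.3, -0.1, 0.25, 0.7, -0.6, 0.2),
                c(2, 2, -1, 3, 3, -2),          # heavy ties
                c(-1, -2, -3))
  for (d in cases) {
    got <- wilcoxon_signed_rank(d, alternative = "greater")
    expect_identical(got$method, "exact")
    expect_equal(got$p, wilcoxon_enumeration_oracle(d), tolerance = 1e-12)
  }
  # the canonical all-positive case: statistic 15, p = 1/32
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_identical(w$statistic, 15)
  expect_identical(w$p, 1 / 32)
  # direction contract: all-negative differences cannot support "greater"
  expect_gt(wilcoxon_signed_rank(c(-1, -2, -3), "greater")$p, 0.5)
  # symmetric differences give no evidence of a positive shift
  expect_gte(wilcoxon_signed_rank(c(1, -1, 2, -2), "greater")$p, 0.5)
})

test_that("the exact tail agrees with stats::wilcox.test when ties are absent", {
  withr::with_seed(17, {
    for (i in 1:10) {
      d <- round(runif(8, -1, 1), 3)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      ours <- wilcoxon_signed_rank(d, "greater")$p
      ref <- stats::wilcox.test(d, alternative = "greater", exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("the large-n normal approximation is sane and tie-corrected", {
  withr::with_seed(18, d <- rnorm(40, mean = 0.5))
  got <- wilcoxon_signed_rank(d, "greater")
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(got$p, ref, tolerance = 1e-6)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "undefined")
})

test_that("a separable task scores a cross-validated MCC of 1", {
  y <- rep(c(1L, 0L), each = 20)
  withr::with_seed(61, noise <- matrix(rbinom(40 * 5, 1, 0.5), nrow = 40))
  mat <- cbind(as.integer(y), noise)
  fp <- aicmax:::fingerprint_tibble(mat, sprintf("c%02d", 1:40), 0:5)
  ds <- labeled_dataset(fp, y)
  expect_identical(cross_validated_mcc(ds, learner = learner_stump(),
                                       folds = 10, seed = 1), 1)
  # restricting to the perfect bit preserves the result
  expect_identical(cross_validated_mcc(ds, bits = 0, learner = learner_stump(),
                                       folds = 10, seed = 1), 1)
})

test_that("cross-validated MCC is deterministic given a seed", {
  suite <- generate(synthetic_spec(
    30, 30,
    planted_bits = tibble::tibble(bit = 0L, p_active = 0.8, p_inactive = 0.2),
    n_noise_bits = 10, seed = 9))
  ds <- suite$tasks[[1]]
  a <- cross_validated_mcc(ds, learner = learner_random_forest(num_trees = 50),
                           folds = 5, seed = 11)
  b <- cross_validated_mcc(ds, learner = learner_random_forest(num_trees = 50),
                           folds = 5, seed = 11)
  expect_identical(a, b)
})

test_that("labels shuffled independently of the bits give near-zero MCC", {
  withr::with_seed(71, {
    mat <- matrix(rbinom(500 * 20, 1, 0.4), nrow = 500)
    y <- sample(rep(c(0L, 1L), each = 250))
  })
  fp <- aicmax:::fingerprint_tibble(mat, sprintf("c%03d", 1:500), 0:19)
  m <- cross_validated_mcc(labeled_dataset(fp, y), learner = learner_stump(),
                           folds = 10, seed = 2)
  expect_lt(abs(m), 0.15)
})

test_that("fold counts shrink with a warning for small classes", {
  y <- c(rep(1L, 3), rep(0L, 20))
  fp <- random_fingerprints(23, 4, seed = 81)
  ds <- labeled_dataset(fp, y)
  w <- testthat::capture_warnings(
    cross_validated_mcc(ds, learner = learner_stump(), folds = 10, seed = 1))
  expect_true(any(grepl("reducing folds", w)))
  tiny <- labeled_dataset(random_fingerprints(5, 3, seed = 82),
                          c(1L, 0L, 0L, 0L, 0L))
  expect_error(suppressWarnings(
    cross_validated_mcc(tiny, learner = learner_stump(), folds = 5, seed = 1)),
    "at least 2")
})

test_that("identity subsets yield all-nc reports with the test skipped", {
  suite <- generate(synthetic_spec(
    20, 20,
    planted_bits = tibble::tibble(bit = 0L, p_active = 0.9, p_inactive = 0.1),
    n_noise_bits = 5, n_targets = 3, seed = 13))
  all_bits <- as.integer(names(suite$tasks[[1]]$fingerprints)[-1])
  subsets <- setNames(rep(list(all_bits), 3),
                      vapply(suite$tasks, `[[`, character(1), "task_id"))
  rep <- compare_representations(suite$tasks, subsets,
                                 learner = learner_stump(), folds = 5, seed = 3)
  expect_identical(rep$n_nc, 3L)
  expect_identical(rep$n_improved + rep$n_worse, 0L)
  expect_identical(rep$wilcoxon_method, "skipped")
  expect_true(is.na(rep$wilcoxon_p))
})

test_that("report bookkeeping matches a hand tally and is reproducible", {
  suite <- generate(synthetic_spec(
    25, 25,
    planted_bits = tibble::tibble(bit = 0:1, p_active = c(0.9, 0.7),
                                  p_inactive = c(0.1, 0.3)),
    n_noise_bits = 30, n_targets = 4, seed = 14))
  subsets <- setNames(rep(list(c(0L, 1L)), 4),
                      vapply(suite$tasks, `[[`, character(1), "task_id"))
  r1 <- compare_representations(suite$tasks, subsets, learner = learner_stump(),
                                folds = 5, seed = 7)
  r2 <- compare_representations(suite$tasks, subsets, learner = learner_stump(),
                                folds = 5, seed = 7)
  expect_identical(r1$per_task, r2$per_task)
  expect_identical(r1$wilcoxon_p, r2$wilcoxon_p)
  expect_identical(r1$n_improved + r1$n_worse + r1$n_nc, 4L)
  # signs agree with the deltas under the declared tolerance
  expect_identical(r1$per_task$sign,
                   ifelse(r1$per_task$delta > 0.005, "+",
                          ifelse(r1$per_task$delta < -0.005, "-", "nc")))
  # per-task MCCs match direct recomputation at the same seeds
  for (i in seq_along(suite$tasks)) {
    expect_identical(r1$per_task$mcc_raw[i],
                     cross_validated_mcc(suite$tasks[[i]], NULL,
                                         learner_stump(), 5, seed = 7 + i))
  }
  expect_error(compare_representations(suite$tasks, subsets[1:2]),
               "no reduced subset")
})

test_that("evaluation reports serialize and tidy", {
  suite <- generate(synthetic_spec(
    15, 15,
    planted_bits = tibble::tibble(bit = 0L, p_active = 0.9, p_inactive = 0.1),
    n_noise_bits = 8, n_targets = 2, seed = 15))
  subsets <- setNames(rep(list(0L), 2),
                      vapply(suite$tasks, `[[`, character(1), "task_id"))
  rep <- compare_representations(suite$tasks, subsets, learner = learner_stump(),
                                 folds = 5, seed = 8)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_report(rep, jf, tf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_identical(back$n_improved + back$n_worse + back$n_nc, 2L)
  tab <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_identical(tidy(rep), rep$per_task)
  expect_identical(glance(rep)$n_tasks, 2L)
})
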