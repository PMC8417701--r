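# Validation designs: ecological split geometry, enumeration, the four
# cross-validation procedures, adjusted chance level, time separation.

test_that("ecological split cuts each phase-condition into near-equal thirds", {
  tbl <- toy_table(n_per_block = 80)     # 80 epochs per block
  sp <- make_ecological_split(tbl)
  for (phase in c("train", "test")) for (cond in c("LOW", "HIGH")) {
    sizes <- unname(lengths(sp[[phase]][[cond]]$S))
    expect_equal(sort(sizes, decreasing = TRUE), c(27, 27, 26))
    # groups pair adjacent subsets; every epoch sits in exactly 2 groups
    membership <- table(unlist(sp[[phase]][[cond]]$G))
    expect_true(all(membership == 2))
    expect_equal(length(membership), 80)
  }
})

test_that("training epochs strictly precede testing epochs per condition", {
  for (ord in list(c("LOW", "HIGH", "LOW", "HIGH"),
                   c("HIGH", "LOW", "HIGH", "LOW"))) {
    sp <- make_ecological_split(toy_table(order = ord))
    expect_true(check_time_separation(sp))
    a <- sp$time_separation
    expect_true(all(a$max_train_time < a$min_test_time))
  }
  # participant with too few blocks
  bad <- toy_table()[1:40, ]
  expect_error(make_ecological_split(bad), "4 task blocks")
})

test_that("group combinations enumerate 9 + 9 and 81 ordered pairs", {
  sp <- make_ecological_split(toy_table())
  enum <- enumerate_train_test_pairs(sp)
  expect_equal(nrow(enum$train_combos), 9)
  expect_equal(nrow(enum$test_combos), 9)
  expect_equal(nrow(enum$pairs), 81)
  # train-major deterministic order
  expect_equal(enum$pairs$train_idx, rep(1:9, each = 9))
  expect_equal(enum$pairs$test_idx, rep(1:9, times = 9))
  # degenerate single-group configuration
  enum1 <- enumerate_train_test_pairs(sp, n_groups = 1)
  expect_equal(nrow(enum1$pairs), 1)
})

test_that("traditional intra CV returns 10 fold accuracies near the truth", {
  tbl <- toy_table(effect = 3, seed = 21)
  acc <- traditional_intra_cv(tbl, c("f1", "f2", "f3"), "LDA", seed = 2)
  expect_length(acc, 10)
  expect_gt(mean(acc), 0.9)
  expect_true(all(acc >= 0 & acc <= 1))
  # permuted labels: accuracy within the adjusted chance band
  null_acc <- vapply(1:4, function(s) {
    tb <- toy_table(effect = 0, seed = 30 + s)
    mean(traditional_intra_cv(tb, c("f1", "f2", "f3"), "LDA", seed = s))
  }, numeric(1))
  lvl <- adjusted_chance_level(nrow(tbl), alpha = 0.01)$level
  expect_lt(mean(null_acc), lvl)
  expect_gt(mean(null_acc), 1 - lvl)
})

test_that("ecological intra CV produces 81 time-separated scores", {
  tbl <- toy_table(effect = 2, seed = 22)
  acc <- ecological_intra_cv(tbl, c("f1", "f2"), "GNB", seed = 1)
  expect_length(acc, 81)
  expect_true(check_time_separation(acc))
  expect_gt(mean(acc), 0.8)
})

test_that("ecological intra accuracy degrades as feature drift grows", {
  mean_acc <- vapply(c(0, 2, 6), function(dr) {
    accs <- vapply(1:3, function(s) {
      tb <- toy_table(effect = 1.5, drift = dr, seed = 50 + s)
      mean(ecological_intra_cv(tb, c("f1", "f2", "f3"), "LDA", seed = s))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) < 0))
})

test_that("leave-2-out folds cover all unordered pairs", {
  expect_length(inter_folds(sprintf("P%d", 1:13)), 78)
  expect_length(inter_folds(sprintf("P%d", 1:4)), 6)
  expect_error(inter_folds(c("a", "b")), "at least")
})

test_that("traditional inter CV tests each held-out participant separately", {
  coh <- toy_cohort(4, effect = 2)
  res <- inter_cv(coh, c("f1", "f2", "f3"), "LDA",
                  design = "traditional", seed = 3)
  expect_equal(nrow(res), 12)            # C(4,2) folds x 2 participants
  expect_equal(as.vector(table(res$test_participant)), rep(3L, 4))
  expect_true(all(res$n_test == 80))     # full table of the held-out
  expect_gt(mean(res$accuracy), 0.9)
})

test_that("ecological inter CV transfers first blocks and tests last blocks", {
  coh <- toy_cohort(4, effect = 2)
  res <- inter_cv(coh, c("f1", "f2", "f3"), "LDA",
                  design = "ecological", seed = 3)
  expect_equal(nrow(res), 12)
  expect_true(all(res$n_test == 40))     # only the last LOW + HIGH blocks
  expect_true(check_time_separation(res))
})

test_that("adjusted chance level matches the exact binomial oracle", {
  oracle <- function(n, alpha) {
    cdf <- cumsum(dbinom(0:n, n, 0.5))
    k_star <- which(cdf >= 1 - alpha)[1] - 1
    k_star / n
  }
  for (n in c(20, 40, 80, 160, 320))
    expect_equal(adjusted_chance_level(n)$level, oracle(n, 0.05),
                 label = paste("n =", n))
  lv <- vapply(c(20, 40, 80, 160, 320),
               function(n) adjusted_chance_level(n)$level, numeric(1))
  expect_true(all(diff(lv) < 0))
  expect_true(all(lv >= 0.5))
  expect_gt(adjusted_chance_level(40)$level, adjusted_chance_level(160)$level)
  # large-n limit approaches 0.5
  expect_lt(adjusted_chance_level(1e5)$level, 0.503)
  expect_error(adjusted_chance_level(100, alpha = 1.5), "alpha")
  expect_error(adjusted_chance_level(0), "n_trials")
})

test_that("run_benchmark fills the requested factorial with coherent cells", {
  coh <- toy_cohort(3, effect = 1.5)
  sets <- list(A = c("f1", "f2"), B = c("f1", "f2", "f3"))
  bm <- run_benchmark(coh, sets = sets, classifiers = c("LDA", "GNB"),
                      seed = 11)
  expect_equal(nrow(bm), 2 * 2 * 2 * 2)
  expect_true(all(bm$mean >= 0 & bm$mean <= 1))
  for (i in seq_len(nrow(bm))) {
    acc <- bm$accuracies[[i]]
    expect_equal(bm$n_eval[i], length(acc))
    expect_gte(bm$mean[i], min(acc))
    expect_lte(bm$mean[i], max(acc))
    expect_equal(bm$mean[i], mean(acc))
  }
  # replaying with the same seed reproduces every accuracy exactly
  bm2 <- run_benchmark(coh, sets = sets, classifiers = c("LDA", "GNB"),
                       seed = 11)
  expect_identical(bm$accuracies, bm2$accuracies)
  # intra evaluation counts: traditional 3x10, ecological 3x81
  expect_equal(unique(bm$n_eval[bm$design == "traditional" &
                                  bm$scope == "intra"]), 30)
  expect_equal(unique(bm$n_eval[bm$design == "ecological" &
                                  bm$scope == "intra"]), 243)
})
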