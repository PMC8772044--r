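test_that("per-target trees fit, score by leaf fraction, and refuse single-class input", {
  # perfectly separable by one bit
  D <- matrix(0, 12, 6, dimnames = list(paste0("d", 1:12), paste0("b", 1:6)))
  D[1:6, 3] <- 1
  y <- c(rep(1, 6), rep(0, 6))
  m <- fit_target_tree(D, y, target_id = "tX")
  sc <- score_target_tree(m, D)
  expect_equal(auc(sc, y), 1)
  expect_true(all(sc %in% c(0, 1)))
  expect_equal(m$train_positive_count, 6)

  # single-class column raises the typed condition
  expect_error(fit_target_tree(D, rep(0, 12)), class = "mcsdti_unfittable")
  expect_error(fit_target_tree(D, rep(1, 12)), class = "mcsdti_unfittable")

  # constant features: root-only tree scoring the positive prevalence
  Dc <- matrix(1, 10, 3, dimnames = list(paste0("d", 1:10), paste0("b", 1:3)))
  yc <- c(rep(1, 3), rep(0, 7))
  mc <- fit_target_tree(Dc, yc)
  expect_equal(unname(score_target_tree(mc, Dc)), rep(0.3, 10))

  # dimension mismatch is an error
  expect_error(score_target_tree(m, D[, 1:3]), "feature columns")

  # scores are invariant to drug ordering
  perm <- sample(nrow(D))
  expect_equal(score_target_tree(m, D[perm, ]), sc[perm])
})

test_that("tree scores on feature-independent labels are null", {
  hold <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      D <- matrix(rbinom(40 * 20, 1, 0.3), 40, 20,
                  dimnames = list(paste0("d", 1:40), paste0("b", 1:20)))
      y <- rbinom(40, 1, 0.4)
      if (length(unique(y[1:30])) < 2 || length(unique(y[31:40])) < 2) return(NA_real_)
      m <- fit_target_tree(D[1:30, ], y[1:30])
      auc(score_target_tree(m, D[31:40, ]), y[31:40])
    })
  }, numeric(1))
  expect_lt(abs(mean(hold, na.rm = TRUE) - 0.5), 0.12)
})

test_that("a fold scores only TWLNI targets and skips unfittable columns", {
  d <- generate_dataset(small_config(seed = 3))
  part <- partition_targets(d$Y, 1)
  folds <- make_drug_folds(rownames(d$Y), k = 5, seed = 3)
  test_drugs <- names(folds$assignments)[folds$assignments == 1]
  train_drugs <- setdiff(rownames(d$Y), test_drugs)
  sc <- run_twlni_fold(d$D, d$Y, part, train_drugs, test_drugs)
  expect_setequal(sc$target_ids, part$twlni_ids)
  expect_setequal(sc$drug_ids, test_drugs)
  # any target whose training column is single-class must be unmasked
  for (tj in part$twlni_ids) {
    single <- length(unique(d$Y[train_drugs, tj])) < 2
    expect_equal(all(sc$mask[, tj]), !single)
    if (single) expect_true(tj %in% attr(sc, "skipped"))
  }
  expect_error(run_twlni_fold(d$D, d$Y, part, train_drugs,
                              c(test_drugs, train_drugs[1])))
  # empty TWLNI set: warning and empty score matrix
  part_max <- partition_targets(d$Y, max(count_target_interactions(d$Y)))
  expect_warning(sc0 <- run_twlni_fold(d$D, d$Y, part_max, train_drugs, test_drugs),
                 "empty")
  expect_length(sc0$target_ids, 0)
})

test_that("TWLNI training depends only on the target's own column and never on test labels", {
  d <- generate_dataset(small_config(seed = 6))
  part <- partition_targets(d$Y, 1)
  folds <- make_drug_folds(rownames(d$Y), k = 5, seed = 6)
  test_drugs <- names(folds$assignments)[folds$assignments == 1]
  train_drugs <- setdiff(rownames(d$Y), test_drugs)
  sc <- run_twlni_fold(d$D, d$Y, part, train_drugs, test_drugs)
  tj <- part$twlni_ids[1]

  # scramble every OTHER column of Y: tj's scores must not move
  Y2 <- unclass(d$Y)
  other <- setdiff(colnames(Y2), tj)
  Y2[, other] <- withr::with_seed(1, Y2[sample(nrow(Y2)), other])
  sc2 <- run_twlni_fold(d$D, interaction_matrix(Y2), part, train_drugs, test_drugs)
  expect_identical(sc2$scores[, tj], sc$scores[, tj])

  # flip all test-drug labels: no score may change
  Y3 <- unclass(d$Y)
  Y3[test_drugs, ] <- 1 - Y3[test_drugs, ]
  sc3 <- run_twlni_fold(d$D, interaction_matrix(Y3), part, train_drugs, test_drugs)
  expect_identical(sc3$scores, sc$scores)
})

test_that("macro evaluation averages per-target AUCs and reports exclusions", {
  scores <- matrix(c(0.9, 0.1, 0.8, 0.2,   # t1: perfect
                     0.2, 0.8, 0.1, 0.9,   # t2: inverted
                     0.5, 0.5, 0.5, 0.5),  # t3: all ties
                   nrow = 4,
                   dimnames = list(paste0("d", 1:4), paste0("t", 1:3)))
  Y <- interaction_matrix(matrix(c(1, 0, 1, 0,
                                   1, 0, 1, 0,
                                   1, 0, 1, 0), nrow = 4,
                                 dimnames = dimnames(scores)))
  part <- structure(list(tau = 0L, twlni_ids = paste0("t", 1:3),
                         twsni_ids = character(), counts = c(t1 = 2L, t2 = 2L, t3 = 2L)),
                    class = "target_partition")
  ev <- evaluate_twlni(score_matrix(scores), Y, part)
  expect_equal(unname(ev$per_target), c(1, 0, 0.5))
  expect_equal(ev$macro_auc, 0.5)
  # single-class test labels are excluded from the mean
  Y2 <- unclass(Y); Y2[, "t2"] <- 1
  ev2 <- evaluate_twlni(score_matrix(scores), interaction_matrix(Y2), part)
  expect_equal(ev2$macro_auc, mean(c(1, 0.5)))
  expect_true("t2" %in% ev2$excluded)
  # macro mean of two targets with AUC 0.8 and 1.0 is 0.9; one target -> itself
  expect_equal(mean(c(0.8, 1)), 0.9)
  ev3 <- evaluate_twlni(score_matrix(scores[, "t1", drop = FALSE]), Y, part)
  expect_equal(ev3$macro_auc, 1)
  # all excluded -> typed no-evaluable-targets result
  Yc <- unclass(Y); Yc[] <- 1
  ev4 <- evaluate_twlni(score_matrix(scores), interaction_matrix(Yc), part)
  expect_true(is.na(ev4$macro_auc))
  expect_equal(ev4$reason, "no-evaluable-targets")
})

test_that("macro AUC is invariant to target order and monotone score transforms", {
  d <- generate_dataset(small_config(seed = 12))
  part <- partition_targets(d$Y, 1)
  folds <- make_drug_folds(rownames(d$Y), k = 4, seed = 12)
  test_drugs <- names(folds$assignments)[folds$assignments == 2]
  train_drugs <- setdiff(rownames(d$Y), test_drugs)
  sc <- run_twlni_fold(d$D, d$Y, part, train_drugs, test_drugs)
  ev <- evaluate_twlni(sc, d$Y, part)
  # permute target columns
  perm <- sample(length(sc$target_ids))
  sc_p <- score_matrix(sc$scores[, perm, drop = FALSE], sc$mask[, perm, drop = FALSE])
  expect_equal(evaluate_twlni(sc_p, d$Y, part)$macro_auc, ev$macro_auc)
  # strictly monotone transform within each target
  sc_m <- score_matrix(plogis(3 * sc$scores - 1), sc$mask)
  expect_equal(evaluate_twlni(sc_m, d$Y, part)$macro_auc, ev$macro_auc)
})
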