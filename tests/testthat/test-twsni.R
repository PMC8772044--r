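make_sim <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  similarity_matrix(m)
}

test_that("nearest neighbour maximizes similarity with deterministic ties", {
  S <- make_sim(rbind(c(1, 0.2, 0.9),
                      c(0.2, 1, 0.5),
                      c(0.9, 0.5, 1)), c("q", "a", "b"))
  nb <- nearest_neighbor(S, "q", c("a", "b"))
  expect_equal(nb$neighbor_id, "b")
  expect_equal(nb$similarity, 0.9)
  # exact tie: lexicographically smallest identifier
  S2 <- make_sim(rbind(c(1, 0.5, 0.5),
                       c(0.5, 1, 0),
                       c(0.5, 0, 1)), c("q", "b", "a"))
  expect_equal(nearest_neighbor(S2, "q", c("a", "b"))$neighbor_id, "a")
  # the query itself is excluded even though self-similarity 1 is maximal
  expect_equal(nearest_neighbor(S, "q", c("q", "a"))$neighbor_id, "a")
  expect_error(nearest_neighbor(S, "q", "q"), "no candidates")
})

test_that("profile transfer rules reproduce hand-worked values", {
  drugs <- paste0("d", 1:3)
  targets <- c("tnew", "tstar")
  Y <- interaction_matrix(matrix(c(0, 0, 0, 1, 0, 1), 3,
                                 dimnames = list(drugs, targets)))
  S_t <- make_sim(rbind(c(1, 0.7), c(0.7, 1)), targets)
  # target side: S_t(tnew, t*) = 0.7 times column [1, 0, 1]
  col <- np_target_side(S_t, Y, "tnew", targets)
  expect_equal(unname(col[drugs]), c(0.7, 0, 0.7))
  expect_equal(attr(col, "neighbor")$neighbor_id, "tstar")
  # similarity 0 -> zero column; similarity 1 -> copied column
  S0 <- make_sim(diag(2), targets)
  expect_equal(unname(np_target_side(S0, Y, "tnew", targets)[drugs]), c(0, 0, 0))
  S1 <- make_sim(matrix(1, 2, 2), targets)
  expect_equal(unname(np_target_side(S1, Y, "tnew", targets)[drugs]),
               unname(Y[, "tstar"]))

  # drug side: S_d = 0.8, neighbour row [1, 1, 0] -> [0.8, 0.8, 0]
  Y2 <- interaction_matrix(matrix(c(1, 0, 1, 0, 0, 0), 2, byrow = FALSE,
                                  dimnames = list(c("dstar", "dnew"),
                                                  c("ta", "tb", "tc"))))
  Y2m <- unclass(Y2); Y2m["dstar", ] <- c(1, 1, 0)
  Y2 <- interaction_matrix(Y2m)
  S_d <- make_sim(rbind(c(1, 0.8), c(0.8, 1)), c("dstar", "dnew"))
  row <- np_drug_side(S_d, Y2, "dnew", "dstar")
  expect_equal(as.numeric(row), c(0.8, 0.8, 0))
  # zero similarity or an all-zero neighbour row give zero scores
  S_d0 <- make_sim(diag(2), c("dstar", "dnew"))
  expect_equal(as.numeric(np_drug_side(S_d0, Y2, "dnew", "dstar")), c(0, 0, 0))

  # pair combination is the arithmetic mean
  expect_equal(np_pair_score(0.8, 0), 0.4)
  expect_equal(np_pair_score(0.3, 0.3), 0.3)
  expect_equal(np_pair_score(0, 0), 0)
})

test_that("fold scoring chains the two transfer rules over training data only", {
  # micro-example: S_d(dnew, d*) = 0.8, Y(d*, t) = 1, Y(d*, t*) = 0,
  # S_t(t, t*) = 0.5 -> drug side 0.8, target side 0.5 * (0.8 * 0) = 0,
  # final score 0.4
  drugs <- c("dstar", "dnew")
  targets <- c("t", "tstar")
  Y <- interaction_matrix(matrix(c(1, 0, 0, 0), 2,
                                 dimnames = list(drugs, targets)))
  S_d <- make_sim(rbind(c(1, 0.8), c(0.8, 1)), drugs)
  S_t <- make_sim(rbind(c(1, 0.5), c(0.5, 1)), targets)
  sc <- run_twsni_fold(S_d, S_t, Y, train_drugs = "dstar", test_drugs = "dnew")
  expect_equal(unname(sc$scores["dnew", "t"]), 0.4)
  # and for t*: drug side 0.8 * 0 = 0, target side 0.5 * 0.8 = 0.4, mean 0.2
  expect_equal(unname(sc$scores["dnew", "tstar"]), 0.2)
  expect_true(all(sc$mask))

  # a duplicate training drug with an identical fingerprint row transfers
  # with similarity 1
  drugs3 <- c("a", "b", "c")
  Y3 <- interaction_matrix(matrix(c(1, 1, 0, 0, 1, 0), 3,
                                  dimnames = list(drugs3, c("t1", "t2"))))
  S_d3 <- make_sim(rbind(c(1, 0.1, 1), c(0.1, 1, 0.1), c(1, 0.1, 1)), drugs3)
  S_t3 <- make_sim(diag(2), c("t1", "t2"))
  sc3 <- run_twsni_fold(S_d3, S_t3, Y3, train_drugs = c("a", "b"),
                        test_drugs = "c")
  # identity-off-diagonal S_t: final score is half the drug side everywhere
  expect_equal(unname(sc3$scores["c", ]), unname(1 * Y3["a", ]) / 2)
})

test_that("scores never leave [0,1] and never read test labels", {
  d <- generate_dataset(small_config(seed = 8))
  folds <- make_drug_folds(rownames(d$Y), k = 5, seed = 8)
  test_drugs <- names(folds$assignments)[folds$assignments == 1]
  train_drugs <- setdiff(rownames(d$Y), test_drugs)
  sc <- run_twsni_fold(d$S_d, d$S_t, d$Y, train_drugs, test_drugs)
  expect_true(all(sc$scores >= 0 & sc$scores <= 1))
  # flipping test rows of Y must not change any score
  Y2 <- unclass(d$Y)
  Y2[test_drugs, ] <- 1 - Y2[test_drugs, ]
  sc2 <- run_twsni_fold(d$S_d, d$S_t, interaction_matrix(Y2), train_drugs, test_drugs)
  expect_identical(sc2$scores, sc$scores)
  # degenerate all-zero off-diagonal similarity warns and scores 0
  n <- nrow(d$Y)
  S0 <- similarity_matrix(diag(n), ids = rownames(d$Y))
  expect_warning(sc0 <- run_twsni_fold(S0, d$S_t, d$Y, train_drugs, test_drugs),
                 "degenerate")
  expect_true(all(sc0$scores == 0))
})

test_that("pooled TWSNI evaluation matches its definition", {
  scores <- matrix(c(0.9, 0.8, 0.2, 0.1), 2,
                   dimnames = list(c("d1", "d2"), c("t1", "t2")))
  Y <- interaction_matrix(matrix(c(1, 1, 0, 0), 2, dimnames = dimnames(scores)))
  part <- structure(list(tau = 5L, twlni_ids = character(),
                         twsni_ids = c("t1", "t2"),
                         counts = c(t1 = 2L, t2 = 0L)), class = "target_partition")
  ev <- evaluate_twsni(score_matrix(scores), Y, part)
  expect_equal(ev$pooled_auc, 1)       # all positives above all negatives
  expect_equal(ev$n_pairs, 4L)
  expect_equal(ev$n_positive, 2L)
  # constant scores: midranks give 0.5
  evc <- evaluate_twsni(score_matrix(matrix(0.5, 2, 2, dimnames = dimnames(scores))),
                        Y, part)
  expect_equal(evc$pooled_auc, 0.5)
  # single-class pool is flagged, not a number
  Y1 <- interaction_matrix(matrix(1, 2, 2, dimnames = dimnames(scores)))
  ev1 <- evaluate_twsni(score_matrix(scores), Y1, part)
  expect_true(is.na(ev1$pooled_auc))
  expect_equal(ev1$reason, "pooled-pairs-single-class")
})
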