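# TWLNI strategy: each high-degree target gets its own CART decision tree,
# trained only on that target's own column of Y over the training drugs.
# Neighbouring targets' samples are deliberately never pooled in: in a
# sparse interaction matrix they would contribute far more negatives than
# positives around this target's positives. Evaluation is macro-averaged:
# one AUC per target over its test drugs, then the mean over evaluable
# targets.

#' Decision-tree hyperparameters for per-target models
#'
#' Defaults emulate MATLAB's `fitctree` defaults (the conventional anchor
#' for DTI decision-tree baselines): Gini impurity, minimum parent size 10,
#' minimum leaf size 1, no complexity pruning, no depth cap beyond rpart's
#' hard limit of 30.
#'
#' @param minsplit minimum node size eligible for a split.
#' @param minbucket minimum leaf size.
#' @param cp complexity parameter (0 disables pruning).
#' @param maxdepth maximum tree depth (rpart caps this at 30).
#' @return an `rpart.control` list.
#' @export
tree_control <- function(minsplit = 10L, minbucket = 1L, cp = 0, maxdepth = 30L) {
  rpart::rpart.control(minsplit = minsplit, minbucket = minbucket, cp = cp,
                       maxdepth = maxdepth, xval = 0L)
}

#' Condition signalled when a target column cannot support a classifier
#' @param target_id identifier of the offending target.
#' @param reason human-readable reason.
#' @keywords internal
unfittable_condition <- function(target_id, reason) {
  structure(class = c("mcsdti_unfittable", "error", "condition"),
            list(message = sprintf("target %s unfittable: %s", target_id, reason),
                 call = NULL, target_id = target_id))
}

#' Fit a per-target decision tree
#'
#' Trains a CART tree on the drug feature rows with this target's own
#' interaction column as the class label. Requires both classes to be
#' present; a single-class column raises a typed `"mcsdti_unfittable"`
#' condition so the caller can decide to skip the target.
#'
#' @param D_train drug feature rows (matrix, drugs x p) for the training
#'   drugs.
#' @param y_column binary labels, one per training drug.
#' @param target_id identifier used in the model and in error messages.
#' @param control an [tree_control()] list.
#' @return a `target_model` with the fitted tree and the positive count.
#' @export
fit_target_tree <- function(D_train, y_column, target_id = "target",
                            control = tree_control()) {
  stopifnot(nrow(D_train) == length(y_column))
  if (length(unique(y_column)) < 2L) {
    stop(unfittable_condition(target_id, "training labels are single-class"))
  }
  df <- as.data.frame(D_train)
  df$.y <- factor(y_column, levels = c(0, 1))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"), control = control)
  structure(list(target_id = target_id, tree = fit,
                 train_positive_count = sum(y_column == 1),
                 feature_names = colnames(D_train)),
            class = "target_model")
}

#' Score drugs with a fitted per-target tree
#'
#' The ranking score of a drug is the positive-class fraction of the leaf it
#' falls into (class trees output a hard label; the leaf fraction is the
#' natural continuous score for AUC).
#'
#' @param model a `target_model` from [fit_target_tree()].
#' @param D_test drug feature rows to score.
#' @return numeric vector of scores in \[0, 1\], named by drug id.
#' @export
score_target_tree <- function(model, D_test) {
  stopifnot(inherits(model, "target_model"))
  if (!identical(colnames(D_test), model$feature_names)) {
    stop("feature columns of the test matrix do not match training", call. = FALSE)
  }
  pr <- stats::predict(model$tree, newdata = as.data.frame(D_test), type = "prob")
  stats::setNames(pr[, "1"], rownames(D_test))
}

#' Score one cross-validation fold with the per-target tree strategy
#'
#' For every TWLNI target whose training column contains both classes, fits
#' a tree on the training drugs only and scores the test drugs. Targets with
#' a single-class training column are skipped (their cells stay unmasked)
#' and reported.
#'
#' @param D drug [feature_matrix()] over all drugs.
#' @param Y [interaction_matrix()] over all drugs and targets.
#' @param partition a [partition_targets()] result.
#' @param train_drugs,test_drugs disjoint drug identifier sets.
#' @param control tree hyperparameters, see [tree_control()].
#' @return a [score_matrix()] over (test drugs x TWLNI targets) with a
#'   `skipped` attribute listing unfittable targets.
#' @export
run_twlni_fold <- function(D, Y, partition, train_drugs, test_drugs,
                           control = tree_control()) {
  stopifnot(length(intersect(train_drugs, test_drugs)) == 0L,
            all(c(train_drugs, test_drugs) %in% rownames(Y)))
  targets <- partition$twlni_ids
  if (length(targets) == 0L) {
    warning("TWLNI target set is empty; nothing to score", call. = FALSE)
  }
  scores <- matrix(NA_real_, length(test_drugs), length(targets),
                   dimnames = list(test_drugs, targets))
  mask <- matrix(FALSE, length(test_drugs), length(targets),
                 dimnames = list(test_drugs, targets))
  D_train <- unclass(D)[train_drugs, , drop = FALSE]
  D_test <- unclass(D)[test_drugs, , drop = FALSE]
  skipped <- character()
  for (tj in targets) {
    y <- Y[train_drugs, tj]
    model <- tryCatch(fit_target_tree(D_train, y, target_id = tj, control = control),
                      mcsdti_unfittable = function(e) NULL)
    if (is.null(model)) {
      skipped <- c(skipped, tj)
      next
    }
    scores[, tj] <- score_target_tree(model, D_test)
    mask[, tj] <- TRUE
  }
  scores[!mask] <- 0
  out <- score_matrix(scores, mask)
  attr(out, "skipped") <- skipped
  out
}

#' Evaluate TWLNI predictions by macro-averaged per-target AUC
#'
#' Computes one AUC per TWLNI target over its test drugs and averages over
#' the targets where an AUC is defined (scored column, both classes present
#' among the test labels). Targets excluded from the mean are listed.
#'
#' @param scores a [score_matrix()] from [run_twlni_fold()].
#' @param Y_test [interaction_matrix()] (or submatrix) holding the test
#'   labels for the scored drugs.
#' @param partition the [partition_targets()] result used for scoring.
#' @return a list with `per_target` (named AUC vector), `macro_auc`,
#'   `excluded` (targets without a defined AUC), and `n_evaluable`;
#'   `macro_auc` is `NA` with reason `"no-evaluable-targets"` when no target
#'   AUC is defined.
#' @export
evaluate_twlni <- function(scores, Y_test, partition) {
  stopifnot(inherits(scores, "score_matrix"))
  targets <- intersect(partition$twlni_ids, scores$target_ids)
  drugs <- scores$drug_ids
  per_target <- stats::setNames(rep(NA_real_, length(targets)), targets)
  excluded <- character()
  for (tj in targets) {
    if (!all(scores$mask[, tj])) {
      excluded <- c(excluded, tj)
      next
    }
    labels <- Y_test[drugs, tj]
    a <- auc(scores$scores[, tj], labels)
    if (is.na(a)) excluded <- c(excluded, tj) else per_target[tj] <- a
  }
  evaluable <- per_target[!is.na(per_target)]
  macro <- if (length(evaluable)) mean(evaluable) else NA_real_
  out <- list(per_target = per_target, macro_auc = macro,
              excluded = excluded, n_evaluable = length(evaluable))
  if (!length(evaluable)) out$reason <- "no-evaluable-targets"
  out
}
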