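# Drug-wise (cold-start) cross-validation harness. Folds partition DRUGS:
# a test drug has no observed interactions at training time, for every
# method. TWLNI and TWSNI are evaluated independently and never pooled into
# one number -- pooling would let the heavily annotated targets dominate.

#' Assign drugs to cross-validation folds
#'
#' Uniformly random balanced assignment (fold sizes differ by at most one),
#' deterministic given the seed.
#'
#' @param drug_ids drug identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `fold_split` list with `k`, `assignments` (named integer vector
#'   of fold indices in `1..k`), `seed`.
#' @export
make_drug_folds <- function(drug_ids, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > length(drug_ids)) {
    stop("k (", k, ") exceeds the number of drugs (", length(drug_ids), ")",
         call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(drug_ids))
  assignments <- stats::setNames(rep_len(seq_len(k), length(drug_ids)),
                                 shuffled)[drug_ids]
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_split")
}

#' Area under the ROC curve (Mann-Whitney, midrank ties)
#'
#' `AUC = (#\{pos > neg\} + 0.5 * #\{pos == neg\}) / (n_pos * n_neg)`,
#' computed via midranks. Returns `NA` (an undefined AUC) when either class
#' is absent.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length.
#' @return AUC in \[0, 1\], or `NA_real_` if undefined.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Brute-force AUC oracle
#'
#' Literal double loop over every (positive, negative) score pair: wins
#' count 1, ties count 0.5. Exists as an independent cross-check for
#' [auc()]; the two must agree to within 1e-12 on any input.
#'
#' @inheritParams auc
#' @return AUC in \[0, 1\], or `NA_real_` if undefined.
#' @export
auc_oracle <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ps <- scores[labels == 1]
  ns <- scores[labels != 1]
  if (length(ps) == 0L || length(ns) == 0L) return(NA_real_)
  wins <- 0
  for (p in ps) {
    for (n in ns) {
      if (p > n) wins <- wins + 1
      else if (p == n) wins <- wins + 0.5
    }
  }
  wins / (length(ps) * length(ns))
}

#' Run the full two-strategy DTI pipeline under drug-wise cross-validation
#'
#' Partitions targets by interaction count on the full matrix (or per
#' training fold), then for each fold scores TWLNI targets with per-target
#' decision trees and TWSNI targets with nearest-profile transfer, and
#' evaluates the two parts independently: macro-averaged per-target AUC for
#' TWLNI, pooled AUC for TWSNI. Fold AUCs are aggregated as mean and sample
#' (n-1) standard deviation.
#'
#' @param D drug [feature_matrix()].
#' @param Y [interaction_matrix()].
#' @param S_d,S_t drug and target [similarity_matrix()] objects; when `NULL`
#'   they are computed from the features (`S_d` by Tanimoto on `D`, `S_t` by
#'   Gaussian kernel on `T`).
#' @param T target [feature_matrix()]; only needed when `S_t` is `NULL`.
#' @param tau partition threshold (conventional choices: 1, 3, 5).
#' @param k number of drug folds.
#' @param seed integer seed driving the fold assignment.
#' @param control tree hyperparameters, see [tree_control()].
#' @param partition_per_fold recompute the partition from each training
#'   submatrix instead of the full matrix.
#' @return an `mcsdti_report` list: `config`, `folds` (per-fold detail),
#'   `aggregate` (`twlni`/`twsni` each with `per_fold`, `mean`, `sd`,
#'   `n_folds`, `summary` in "mean +/- sd" form, or `evaluated = FALSE`).
#' @export
run_mcsdti <- function(D, Y, S_d = NULL, S_t = NULL, T = NULL, tau = 1L,
                       k = 5L, seed = 1L, control = tree_control(),
                       partition_per_fold = FALSE) {
  if (is.null(S_d)) S_d <- tanimoto_similarity(D)
  if (is.null(S_t)) {
    if (is.null(T)) stop("either S_t or target features T must be supplied", call. = FALSE)
    S_t <- rbf_similarity(T)
  }
  check_identifier_consistency(Y, D = D, S_d = S_d, S_t = S_t)
  folds <- make_drug_folds(rownames(Y), k = k, seed = seed)
  partition <- partition_targets(Y, tau)

  fold_results <- lapply(seq_len(folds$k), function(f) {
    test_drugs <- names(folds$assignments)[folds$assignments == f]
    train_drugs <- setdiff(rownames(Y), test_drugs)
    part_f <- if (partition_per_fold) {
      partition_targets(interaction_matrix(Y[train_drugs, , drop = FALSE]), tau)
    } else partition
    Y_train <- mask_test_rows(Y, test_drugs)
    twlni_scores <- withCallingHandlers(
      run_twlni_fold(D, Y_train, part_f, train_drugs, test_drugs, control = control),
      warning = function(w) invokeRestart("muffleWarning"))
    twsni_scores <- run_twsni_fold(S_d, S_t, Y_train, train_drugs, test_drugs)
    list(fold = f, test_drugs = test_drugs,
         partition = part_f,
         twlni = evaluate_twlni(twlni_scores, Y, part_f),
         twsni = evaluate_twsni(twsni_scores, Y, part_f),
         twlni_skipped = attr(twlni_scores, "skipped"))
  })

  structure(list(
    config = list(tau = as.integer(tau), k = folds$k, seed = as.integer(seed),
                  partition_per_fold = partition_per_fold,
                  tree_control = unclass(control)[c("minsplit", "minbucket", "cp", "maxdepth")],
                  n_drugs = nrow(Y), n_targets = ncol(Y),
                  n_twlni = length(partition$twlni_ids),
                  n_twsni = length(partition$twsni_ids),
                  fold_assignments = as.list(folds$assignments)),
    folds = fold_results,
    aggregate = list(
      twlni = aggregate_part(vapply(fold_results, function(x) x$twlni$macro_auc, numeric(1))),
      twsni = aggregate_part(vapply(fold_results, function(x) x$twsni$pooled_auc, numeric(1))))),
    class = "mcsdti_report")
}

# Zero out test-drug rows so no stage can see test labels: a cold-start
# test drug has no observed interactions at training/prediction time.
mask_test_rows <- function(Y, test_drugs) {
  Y2 <- unclass(Y)
  Y2[test_drugs, ] <- 0
  interaction_matrix(Y2)
}

aggregate_part <- function(per_fold) {
  vals <- per_fold[!is.na(per_fold)]
  if (!length(vals)) {
    return(list(evaluated = FALSE, per_fold = as.list(per_fold)))
  }
  list(evaluated = TRUE, per_fold = as.list(per_fold),
       mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
       n_folds = length(vals),
       summary = format_mean_sd(vals))
}

format_mean_sd <- function(vals) {
  sprintf("%.4f ± %.4f", mean(vals),
          if (length(vals) > 1L) stats::sd(vals) else 0)
}

check_identifier_consistency <- function(Y, D = NULL, S_d = NULL, S_t = NULL,
                                         T = NULL) {
  if (!is.null(D) && !identical(rownames(D), rownames(Y)))
    stop("drug ids of the feature matrix do not match the interaction matrix",
         call. = FALSE)
  if (!is.null(S_d) && !identical(rownames(S_d), rownames(Y)))
    stop("drug ids of the drug similarity matrix do not match the interaction matrix",
         call. = FALSE)
  if (!is.null(S_t) && !identical(rownames(S_t), colnames(Y)))
    stop("target ids of the target similarity matrix do not match the interaction matrix",
         call. = FALSE)
  if (!is.null(T) && !identical(rownames(T), colnames(Y)))
    stop("target ids of the target feature matrix do not match the interaction matrix",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.mcsdti_report <- function(x, ...) {
  cat(sprintf("<mcsdti_report> tau=%d, %d folds, seed=%d\n",
              x$config$tau, x$config$k, x$config$seed))
  for (part in c("twlni", "twsni")) {
    agg <- x$aggregate[[part]]
    label <- toupper(part)
    if (isTRUE(agg$evaluated)) {
      cat(sprintf("  %s AUC: %s over %d fold(s)\n", label, agg$summary, agg$n_folds))
    } else {
      cat(sprintf("  %s: not evaluated\n", label))
    }
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes a machine-readable JSON document with all per-fold and per-target
#' detail plus the configuration echo, and beside it a plain-text summary in
#' "mean +/- sd" form (same path with extension `.txt`).
#'
#' @param report an `mcsdti_report` from [run_mcsdti()] (or a baseline run).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::serializeJSON(unclass(report), digits = I(17))
  writeLines(json, path)
  txt <- sub("\\.json$", "", path)
  txt <- paste0(txt, ".txt")
  lines <- c(sprintf("tau=%d folds=%d seed=%d", report$config$tau,
                     report$config$k, report$config$seed))
  for (part in c("twlni", "twsni")) {
    agg <- report$aggregate[[part]]
    lines <- c(lines, if (isTRUE(agg$evaluated)) {
      sprintf("%s AUC: %s (n=%d folds)", toupper(part), agg$summary, agg$n_folds)
    } else {
      sprintf("%s: not evaluated", toupper(part))
    })
  }
  writeLines(lines, txt)
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return the `mcsdti_report` object, numerically identical to the one
#'   written.
#' @export
read_report <- function(path) {
  structure(jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n")),
            class = "mcsdti_report")
}
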