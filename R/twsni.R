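# TWSNI strategy: nearest-profile (NP) similarity transfer. A low-degree
# target has too few positives to train on, so its scores are borrowed from
# the single most similar neighbour:
#   target side:  Y(:, t_new) = S_t(t_new, t_nearest) * Y(:, t_nearest)
#   drug side:    Y(d_new, :) = S_d(d_new, d_nearest) * Y(d_nearest, :)
# and a pair score is the mean of the two sides. Only the nearest neighbour
# is used: with imperfect similarity measures, profiles further away are
# less trustworthy, so NP trades variance for robustness to similarity
# miscalibration. All targets participate as transfer sources; only the
# TWSNI part is evaluated.

#' Nearest neighbour under a similarity matrix
#'
#' Returns the candidate maximizing `S[query, candidate]`, excluding the
#' query itself. Ties are broken deterministically by the smallest
#' identifier in sort order.
#'
#' @param S a [similarity_matrix()].
#' @param query_id identifier of the query row.
#' @param candidate_ids candidate identifiers (the query is removed if
#'   present).
#' @return a list `neighbor_lookup` with `query_id`, `neighbor_id`,
#'   `similarity`.
#' @export
nearest_neighbor <- function(S, query_id, candidate_ids) {
  candidate_ids <- setdiff(candidate_ids, query_id)
  if (length(candidate_ids) == 0L) {
    stop("no candidates left after excluding the query", call. = FALSE)
  }
  sims <- S[query_id, candidate_ids]
  best <- sort(candidate_ids[sims == max(sims)])[1L]
  structure(list(query_id = query_id, neighbor_id = best,
                 similarity = unname(S[query_id, best])),
            class = "neighbor_lookup")
}

#' Target-side nearest-profile score column
#'
#' Scores every drug for a query target by copying the nearest candidate
#' target's value column scaled by the similarity:
#' `S_t(t_query, t_nearest) * values[, t_nearest]`.
#'
#' @param S_t target [similarity_matrix()].
#' @param Y_known matrix of known (or previously estimated) values, drugs x
#'   targets.
#' @param t_query query target identifier.
#' @param candidate_targets identifiers with known columns.
#' @return numeric score column named by drug id, with the chosen neighbour
#'   in attribute `"neighbor"`.
#' @export
np_target_side <- function(S_t, Y_known, t_query, candidate_targets) {
  nb <- nearest_neighbor(S_t, t_query, candidate_targets)
  out <- nb$similarity * Y_known[, nb$neighbor_id]
  attr(out, "neighbor") <- nb
  out
}

#' Drug-side nearest-profile score row
#'
#' Scores every target for a query drug by copying the nearest candidate
#' drug's interaction row scaled by the similarity:
#' `S_d(d_query, d_nearest) * Y[d_nearest, ]`.
#'
#' @param S_d drug [similarity_matrix()].
#' @param Y [interaction_matrix()].
#' @param d_query query drug identifier.
#' @param candidate_drugs identifiers of drugs with observed rows (training
#'   drugs).
#' @return numeric score row named by target id, with the chosen neighbour
#'   in attribute `"neighbor"`.
#' @export
np_drug_side <- function(S_d, Y, d_query, candidate_drugs) {
  nb <- nearest_neighbor(S_d, d_query, candidate_drugs)
  out <- nb$similarity * Y[nb$neighbor_id, ]
  attr(out, "neighbor") <- nb
  out
}

#' Combine drug-side and target-side scores for one pair
#'
#' @param drug_side,target_side scores in \[0, 1\].
#' @return their arithmetic mean.
#' @export
np_pair_score <- function(drug_side, target_side) {
  stopifnot(all(is.finite(drug_side)), all(is.finite(target_side)))
  (drug_side + target_side) / 2
}

#' Score one cross-validation fold with nearest-profile transfer
#'
#' For every test drug, the drug-side row comes from its nearest training
#' drug. The target side needs `Y(d_new, t_nearest)`, which is unobserved
#' for a test drug; it is replaced by its own drug-side estimate
#' `S_d(d_new, d_nearest) * Y(d_nearest, t_nearest)`, so the whole
#' computation stays inside the two transfer rules and never touches test
#' labels. Target neighbours are searched among all targets (low-degree
#' targets need the information held by their neighbours); drug neighbours
#' among training drugs only. All (test drug, target) cells are scored --
#' evaluation later restricts to the TWSNI part.
#'
#' @param S_d,S_t drug and target [similarity_matrix()] objects.
#' @param Y [interaction_matrix()].
#' @param train_drugs,test_drugs disjoint drug identifier sets.
#' @return a [score_matrix()] over (test drugs x all targets).
#' @export
run_twsni_fold <- function(S_d, S_t, Y, train_drugs, test_drugs) {
  stopifnot(length(intersect(train_drugs, test_drugs)) == 0L,
            all(c(train_drugs, test_drugs) %in% rownames(Y)),
            length(train_drugs) >= 1L)
  targets <- colnames(Y)
  off_diag <- S_d[train_drugs, train_drugs, drop = FALSE]
  if (length(train_drugs) > 1L && all(off_diag[upper.tri(off_diag)] == 0) &&
      all(S_d[test_drugs, train_drugs] == 0)) {
    warning("degenerate drug similarity (all zeros off-diagonal); scores fall back to 0",
            call. = FALSE)
  }
  # nearest source target for each target, over all targets
  t_near <- lapply(targets, function(tj) nearest_neighbor(S_t, tj, targets))
  names(t_near) <- targets

  scores <- matrix(NA_real_, length(test_drugs), length(targets),
                   dimnames = list(test_drugs, targets))
  for (d in test_drugs) {
    drug_side <- np_drug_side(S_d, Y, d, train_drugs)
    target_side <- vapply(targets, function(tj) {
      nb <- t_near[[tj]]
      nb$similarity * drug_side[[nb$neighbor_id]]
    }, numeric(1))
    scores[d, ] <- np_pair_score(drug_side, target_side)
  }
  score_matrix(scores)
}

#' Evaluate TWSNI predictions by pooled AUC
#'
#' One AUC over the pooled set of (test drug, TWSNI target) pairs. Pooling
#' is used because most TWSNI targets have at most one positive, so a
#' per-target AUC is usually undefined.
#'
#' @param scores a [score_matrix()] covering all targets for the test drugs.
#' @param Y_test [interaction_matrix()] holding the test labels.
#' @param partition the [partition_targets()] result.
#' @return a list with `pooled_auc` (`NA` with a `reason` when the pooled
#'   pair set is single-class or empty), `n_pairs`, `n_positive`.
#' @export
evaluate_twsni <- function(scores, Y_test, partition) {
  stopifnot(inherits(scores, "score_matrix"))
  targets <- intersect(partition$twsni_ids, scores$target_ids)
  if (length(targets) == 0L) {
    return(list(pooled_auc = NA_real_, n_pairs = 0L, n_positive = 0L,
                reason = "no-twsni-targets"))
  }
  s <- as.vector(scores$scores[, targets, drop = FALSE])
  y <- as.vector(Y_test[scores$drug_ids, targets, drop = FALSE])
  a <- auc(s, y)
  out <- list(pooled_auc = a, n_pairs = length(y), n_positive = sum(y == 1))
  if (is.na(a)) out$reason <- "pooled-pairs-single-class"
  out
}
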