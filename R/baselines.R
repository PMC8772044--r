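# Classical comparison methods, run under the identical drug-wise folds and
# the identical two-part evaluators as the main pipeline (fair-comparison
# contract):
#   dt  -- one global CART tree on concatenated [drug || target] pair vectors
#   np  -- nearest profile over the full pair space (the TWSNI scorer)
#   wp  -- weighted profile: similarity-weighted average over ALL candidates
#   nbi -- network-based inference: two-pass degree-normalized resource
#          diffusion on the training bipartite graph (similarity-free)

#' Global decision-tree baseline over pair vectors
#'
#' Trains one CART tree on every (training drug, target) pair, represented
#' by the concatenated drug fingerprint and target descriptor (dimension
#' p + q; 1024 + 1437 = 2461 at the conventional feature defaults), and
#' scores every (test drug, target) pair.
#'
#' @param D drug [feature_matrix()].
#' @param T target [feature_matrix()].
#' @param Y [interaction_matrix()].
#' @param train_drugs,test_drugs disjoint drug identifier sets.
#' @param control tree hyperparameters, see [tree_control()].
#' @return a [score_matrix()] over (test drugs x all targets).
#' @export
global_tree_baseline <- function(D, T, Y, train_drugs, test_drugs,
                                 control = tree_control()) {
  stopifnot(length(intersect(train_drugs, test_drugs)) == 0L)
  X_train <- pair_feature_matrix(D, T, train_drugs)
  y <- as.vector(t(Y[train_drugs, , drop = FALSE]))   # same pair order
  if (length(unique(y)) < 2L) {
    stop("training pairs are single-class; cannot fit the global tree", call. = FALSE)
  }
  df <- as.data.frame(X_train)
  df$.y <- factor(y, levels = c(0, 1))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"), control = control)
  X_test <- pair_feature_matrix(D, T, test_drugs)
  pr <- stats::predict(fit, newdata = as.data.frame(X_test), type = "prob")[, "1"]
  scores <- matrix(pr, nrow = length(test_drugs), ncol = ncol(Y), byrow = TRUE,
                   dimnames = list(test_drugs, colnames(Y)))
  score_matrix(scores)
}

#' Concatenated pair feature vectors for a set of drugs
#'
#' One row per (drug, target) pair, in target-major order within each drug:
#' `[drug fingerprint || target descriptor]`, total dimension `p + q`.
#'
#' @param D drug [feature_matrix()] (u x p).
#' @param T target [feature_matrix()] (v x q).
#' @param drugs drug identifiers to expand.
#' @return numeric matrix with `length(drugs) * nrow(T)` rows and
#'   `ncol(D) + ncol(T)` columns.
#' @export
pair_feature_matrix <- function(D, T, drugs) {
  Dm <- unclass(D)[drugs, , drop = FALSE]
  Tm <- unclass(T)
  v <- nrow(Tm)
  X <- cbind(Dm[rep(seq_along(drugs), each = v), , drop = FALSE],
             Tm[rep(seq_len(v), times = length(drugs)), , drop = FALSE])
  rownames(X) <- paste(rep(drugs, each = v), rep(rownames(Tm), length(drugs)),
                       sep = ":")
  colnames(X) <- c(paste0("d.", colnames(Dm)), paste0("t.", colnames(Tm)))
  X
}

#' Weighted-profile scores for one query
#'
#' Similarity-weighted average of all candidate profiles:
#' `score = sum_c S[query, c] * Y[c, ] / sum_c S[query, c]` (drug axis; the
#' target axis transposes). A zero similarity total yields zero scores with
#' a warning. With a one-hot similarity row this reduces exactly to the
#' nearest-profile transfer scaled by similarity 1.
#'
#' @param S a [similarity_matrix()] over the query axis.
#' @param Y [interaction_matrix()] (or estimated value matrix).
#' @param query_id identifier of the query drug or target.
#' @param axis `"drug"` (rows of `Y`) or `"target"` (columns of `Y`).
#' @param candidates candidate identifiers (the query is excluded).
#' @return numeric score vector over the opposite axis.
#' @export
weighted_profile <- function(S, Y, query_id, axis = c("drug", "target"),
                             candidates) {
  axis <- match.arg(axis)
  candidates <- setdiff(candidates, query_id)
  if (length(candidates) == 0L) stop("no candidates", call. = FALSE)
  w <- S[query_id, candidates]
  profiles <- if (axis == "drug") Y[candidates, , drop = FALSE]
              else t(Y[, candidates, drop = FALSE])
  tot <- sum(w)
  if (tot == 0) {
    warning("all candidate similarities are zero for ", query_id,
            "; scores fall back to 0", call. = FALSE)
    return(stats::setNames(numeric(ncol(profiles)), colnames(profiles)))
  }
  drop(w %*% profiles) / tot
}

#' Score one fold with the weighted-profile baseline
#'
#' Drug side: similarity-weighted average over all training-drug rows.
#' Target side: weighted average over all other targets' columns, where a
#' test drug's unobserved value at a source target is replaced by its
#' drug-side estimate (same chaining as the nearest-profile scorer). The
#' two sides are combined by their mean.
#'
#' @inheritParams run_twsni_fold
#' @return a [score_matrix()] over (test drugs x all targets).
#' @export
run_wp_fold <- function(S_d, S_t, Y, train_drugs, test_drugs) {
  targets <- colnames(Y)
  scores <- matrix(NA_real_, length(test_drugs), length(targets),
                   dimnames = list(test_drugs, targets))
  # target-side weights are shared across drugs
  W_t <- unclass(S_t)
  diag(W_t) <- 0
  tot_t <- colSums(W_t)
  for (d in test_drugs) {
    drug_side <- weighted_profile(S_d, Y, d, axis = "drug",
                                  candidates = train_drugs)
    # chain: estimated profile of d over source targets = drug_side
    target_side <- drop(drug_side %*% W_t)
    target_side <- ifelse(tot_t > 0, target_side / tot_t, 0)
    scores[d, ] <- (drug_side + target_side) / 2
  }
  score_matrix(pmin(pmax(scores, 0), 1))
}

#' Network-based inference scores for one fold
#'
#' Two-pass resource diffusion on the training bipartite interaction graph:
#' each drug's resource spreads to its targets (split equally by drug
#' degree) and back to drugs (split equally by target degree), giving a
#' drug-drug transfer matrix `W`; a test drug's scores are the projection of
#' its training row through `W` -- which is identically zero for a
#' cold-start drug with no training edges (warned, scored 0). Uses no
#' chemical or sequence similarity.
#'
#' @param Y [interaction_matrix()].
#' @param train_drugs,test_drugs disjoint drug identifier sets.
#' @param query_profiles optional matrix of known interaction profiles for
#'   the test drugs (rows named by test drug, columns by target). Under
#'   drug-wise CV a test drug has no observed training edges, so the default
#'   profile is all-zero and the scores are all-zero (with a warning).
#' @return a [score_matrix()] over (test drugs x all targets).
#' @export
nbi_scores <- function(Y, train_drugs, test_drugs, query_profiles = NULL) {
  stopifnot(length(intersect(train_drugs, test_drugs)) == 0L)
  Y_tr <- unclass(Y)[train_drugs, , drop = FALSE]
  if (sum(Y_tr) == 0) stop("training bipartite graph has no interactions", call. = FALSE)
  if (is.null(query_profiles)) {
    query_profiles <- matrix(0, length(test_drugs), ncol(Y),
                             dimnames = list(test_drugs, colnames(Y)))
  }
  cold <- rowSums(query_profiles) == 0
  if (any(cold)) {
    warning(sum(cold), " test drug(s) have no training edges; NBI scores them 0",
            call. = FALSE)
  }
  scores <- nbi_diffuse(Y_tr, query_profiles)
  score_matrix(pmin(scores, 1))
}

#' Two-pass NBI diffusion on a training bipartite graph
#'
#' Given training interactions `Y_train` and one initial resource profile
#' per query drug (its known target set), spreads each unit of resource
#' target -> drug -> target with equal splitting by node degree and returns
#' the final resource over targets. Total resource is conserved in every
#' pass. A query with a single training interaction (d1, t1), where both d1
#' and t1 have degree 1, sends all resource back to where it started.
#'
#' @param Y_train binary matrix, training drugs x targets.
#' @param query_profiles binary matrix, query drugs x targets.
#' @return numeric score matrix, query drugs x targets.
#' @export
nbi_diffuse <- function(Y_train, query_profiles) {
  stopifnot(ncol(Y_train) == ncol(query_profiles))
  k_d <- rowSums(Y_train)                   # drug degrees
  k_t <- colSums(Y_train)                   # target degrees
  # target -> drug: each target splits its resource over its drugs
  P_td <- t(Y_train) / ifelse(k_t > 0, k_t, 1)
  # drug -> target: each drug splits its resource over its targets
  P_dt <- Y_train / ifelse(k_d > 0, k_d, 1)
  out <- query_profiles %*% P_td %*% P_dt
  dimnames(out) <- list(rownames(query_profiles), colnames(Y_train))
  out
}

#' Run a comparison method under the same folds and evaluators
#'
#' Scores the full pair space with the chosen baseline in every fold, then
#' applies exactly the two-part evaluation used for the main pipeline: the
#' TWLNI part by macro-averaged per-target AUC (TWSNI removed) and the
#' TWSNI part by pooled AUC (TWLNI removed), under the identical fold
#' assignments for the same seed.
#'
#' @param method one of `"dt"`, `"np"`, `"wp"`, `"nbi"`.
#' @inheritParams run_mcsdti
#' @return an `mcsdti_report` with an added `config$method` field.
#' @export
run_baseline_cv <- function(method = c("dt", "np", "wp", "nbi"), D = NULL,
                            T = NULL, Y, S_d = NULL, S_t = NULL, tau = 1L,
                            k = 5L, seed = 1L, control = tree_control()) {
  method <- match.arg(method)
  if (method %in% c("np", "wp")) {
    if (is.null(S_d)) S_d <- tanimoto_similarity(D)
    if (is.null(S_t)) {
      if (is.null(T)) stop("either S_t or target features T must be supplied",
                           call. = FALSE)
      S_t <- rbf_similarity(T)
    }
  }
  if (method == "dt" && (is.null(D) || is.null(T))) {
    stop("the global tree baseline needs both feature matrices", call. = FALSE)
  }
  folds <- make_drug_folds(rownames(Y), k = k, seed = seed)
  partition <- partition_targets(Y, tau)
  fold_results <- lapply(seq_len(folds$k), function(f) {
    test_drugs <- names(folds$assignments)[folds$assignments == f]
    train_drugs <- setdiff(rownames(Y), test_drugs)
    Y_train <- mask_test_rows(Y, test_drugs)
    scores <- withCallingHandlers(
      switch(method,
             dt = global_tree_baseline(D, T, Y_train, train_drugs, test_drugs,
                                       control = control),
             np = run_twsni_fold(S_d, S_t, Y_train, train_drugs, test_drugs),
             wp = run_wp_fold(S_d, S_t, Y_train, train_drugs, test_drugs),
             nbi = nbi_scores(Y_train, train_drugs, test_drugs)),
      warning = function(w) invokeRestart("muffleWarning"))
    list(fold = f, test_drugs = test_drugs,
         twlni = evaluate_twlni(scores, Y, partition),
         twsni = evaluate_twsni(scores, Y, partition))
  })
  structure(list(
    config = list(method = method, tau = as.integer(tau), k = folds$k,
                  seed = as.integer(seed), n_drugs = nrow(Y),
                  n_targets = ncol(Y),
                  fold_assignments = as.list(folds$assignments)),
    folds = fold_results,
    aggregate = list(
      twlni = aggregate_part(vapply(fold_results, function(x) x$twlni$macro_auc, numeric(1))),
      twsni = aggregate_part(vapply(fold_results, function(x) x$twsni$pooled_auc, numeric(1))))),
    class = "mcsdti_report")
}
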