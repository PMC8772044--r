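# Synthetic chemogenomic fixtures. The generator reproduces the statistical
# structure DTI prediction depends on -- a sparse binary interaction matrix
# whose per-target degrees are strongly skewed, binary drug fingerprints
# carrying a plantable per-target signal, real-valued protein descriptors --
# without attempting realistic chemistry or biology.

#' Configuration for the synthetic DTI data generator
#'
#' Defaults mirror the smallest public chemogenomic benchmark (nuclear
#' receptors): 54 drugs, 26 targets, 6.4% interaction density, 1024
#' fingerprint bits, 1437 protein descriptors. `skew` is the Zipf-like
#' exponent of the target degree distribution (1 reproduces the documented
#' concentration of roughly half of all interactions on the top 20% of
#' targets); `signal` is the fraction of fingerprint bits informative per
#' target; `noise` is the label-flip probability.
#'
#' @param u,v drug and target counts.
#' @param p,q drug and target feature dimensions.
#' @param density requested interaction proportion in (0, 1).
#' @param skew non-negative power-law exponent for target degrees.
#' @param signal proportion in \[0, 1\] of fingerprint bits informative per
#'   target; 0 plants no signal (null data).
#' @param noise label-flip probability in \[0, 0.5).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(u = 54L, v = 26L, p = 1024L, q = 1437L,
                             density = 0.064, skew = 1, signal = 0.05,
                             noise = 0, seed = 1L) {
  stopifnot(u >= 2L, v >= 2L, p >= 1L, q >= 1L)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]", call. = FALSE)
  if (skew < 0) stop("skew must be non-negative", call. = FALSE)
  if (signal < 0 || signal > 1) stop("signal must lie in [0, 1]", call. = FALSE)
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)", call. = FALSE)
  if (round(u * v * density) < 1) stop("u * v * density must be >= 1", call. = FALSE)
  structure(list(u = as.integer(u), v = as.integer(v), p = as.integer(p),
                 q = as.integer(q), density = density, skew = skew,
                 signal = signal, noise = noise, seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample a skewed per-target interaction degree sequence
#'
#' Apportions `round(u * v * density)` interactions over `v` targets with
#' weights proportional to `rank^-skew` (largest-remainder rounding), caps
#' each count at `u`, and assigns counts to target indices by a seeded
#' permutation. `skew = 0` yields near-uniform counts; `skew >= 1` places the
#' bulk of interactions on a small fraction of targets. The counts always sum
#' exactly to `round(u * v * density)`.
#'
#' @param cfg a [generator_config()].
#' @return integer vector of length `v`.
#' @export
sample_target_degrees <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  total <- round(cfg$u * cfg$v * cfg$density)
  if (total > cfg$u * cfg$v) stop("requested density exceeds 1", call. = FALSE)
  w <- seq_len(cfg$v)^(-cfg$skew)
  counts <- apportion_largest_remainder(total, w, cap = cfg$u)
  withr::with_seed(cfg$seed, counts[sample.int(cfg$v)])
}

# Largest-remainder apportionment of `total` units over weights `w`, each
# share capped at `cap`. Deterministic; exact conservation.
apportion_largest_remainder <- function(total, w, cap) {
  ideal <- total * w / sum(w)
  counts <- floor(ideal)
  rem <- total - sum(counts)
  if (rem > 0) {
    ord <- order(ideal - counts, decreasing = TRUE)
    take <- ord[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  # redistribute any excess above the cap to the next-heaviest headroom
  over <- pmax(counts - cap, 0)
  counts <- pmin(counts, cap)
  excess <- sum(over)
  while (excess > 0) {
    headroom <- cap - counts
    if (all(headroom <= 0)) stop("cannot place ", excess, " interactions: all targets full",
                                 call. = FALSE)
    j <- order(w, decreasing = TRUE)[which(headroom[order(w, decreasing = TRUE)] > 0)[1L]]
    add <- min(excess, headroom[j])
    counts[j] <- counts[j] + add
    excess <- excess - add
  }
  as.integer(counts)
}

#' Generate a complete synthetic DTI dataset
#'
#' Draws the target degree sequence, assigns each target a hidden subset of
#' `signal * p` fingerprint bits, picks its interacting drugs at random, and
#' paints fingerprints so that an interacting drug carries its target's
#' signature bits while every bit otherwise appears at a low background rate
#' (0.1); labels are then flipped with probability `noise`. The label-flip
#' dial is thus the only corruption of the feature-to-label rule: at
#' `noise = 0` the planted signal is exact and recoverable, and raising
#' `noise` degrades it in a controlled way. Target descriptors are Gaussian
#' with a per-target offset. Similarities are derived from the features: Tanimoto over
#' fingerprints for drugs, a Gaussian kernel over descriptors for targets.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return a list with elements `Y` ([interaction_matrix()]), `D` and `T`
#'   ([feature_matrix()]), `S_d` and `S_t` ([similarity_matrix()]), and the
#'   `config` echoed back.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  degrees <- sample_target_degrees(cfg)
  withr::with_seed(cfg$seed + 1L, {
    drug_ids <- sprintf("d%03d", seq_len(cfg$u))
    target_ids <- sprintf("t%03d", seq_len(cfg$v))

    # interacting drugs per target
    interactors <- lapply(degrees, function(k) sample.int(cfg$u, k))

    # hidden informative bit subsets per target
    n_bits <- if (cfg$signal > 0) max(1L, round(cfg$signal * cfg$p)) else 0L
    bit_sets <- lapply(seq_len(cfg$v), function(j) {
      if (n_bits == 0L) integer() else sample.int(cfg$p, n_bits)
    })

    # fingerprints: background rate 0.1; an interactor carries its target's
    # full bit signature (label flips below are the only noise dial)
    prob <- matrix(0.1, cfg$u, cfg$p)
    for (j in seq_len(cfg$v)) {
      if (length(bit_sets[[j]]) && length(interactors[[j]])) {
        prob[interactors[[j]], bit_sets[[j]]] <- 1
      }
    }
    D <- matrix(as.double(stats::runif(cfg$u * cfg$p) < prob), cfg$u, cfg$p,
                dimnames = list(drug_ids, sprintf("bit%04d", seq_len(cfg$p))))

    # labels, then symmetric flip noise
    Y <- matrix(0, cfg$u, cfg$v, dimnames = list(drug_ids, target_ids))
    for (j in seq_len(cfg$v)) Y[interactors[[j]], j] <- 1
    if (cfg$noise > 0) {
      flip <- matrix(stats::runif(cfg$u * cfg$v) < cfg$noise, cfg$u, cfg$v)
      Y[flip] <- 1 - Y[flip]
    }

    # protein descriptors: shared Gaussian background plus a per-target offset
    centers <- matrix(stats::rnorm(cfg$v * cfg$q), cfg$v, cfg$q)
    Tm <- centers + matrix(stats::rnorm(cfg$v * cfg$q, sd = 0.5), cfg$v, cfg$q)
    dimnames(Tm) <- list(target_ids, sprintf("desc%04d", seq_len(cfg$q)))
  })

  D_fm <- feature_matrix(D, kind = "drug")
  T_fm <- feature_matrix(Tm, kind = "target")
  list(Y = interaction_matrix(Y),
       D = D_fm,
       T = T_fm,
       S_d = tanimoto_similarity(D_fm),
       S_t = rbf_similarity(T_fm),
       config = cfg)
}

#' Tanimoto (Jaccard) similarity between binary fingerprints
#'
#' `S[i, j] = |bits_i AND bits_j| / |bits_i OR bits_j|`. A row with an
#' all-zero fingerprint has similarity 0 to every other row and 1 to itself.
#'
#' @param F a binary [feature_matrix()] (rows are drugs).
#' @return a [similarity_matrix()].
#' @export
tanimoto_similarity <- function(F) {
  m <- unclass(F)
  if (!all(m %in% c(0, 1))) stop("Tanimoto requires a binary matrix", call. = FALSE)
  inter <- m %*% t(m)
  sz <- rowSums(m)
  uni <- outer(sz, sz, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- 1
  similarity_matrix(S, ids = rownames(m))
}

#' Gaussian (RBF) similarity between real-valued descriptor rows
#'
#' `S[i, j] = exp(-||x_i - x_j||^2 / bandwidth)`; `bandwidth = "median"` uses
#' the median off-diagonal squared pairwise distance (the usual median
#' heuristic). The diagonal is exactly 1.
#'
#' @param F a real-valued [feature_matrix()] (rows are targets).
#' @param bandwidth positive scalar, or `"median"`.
#' @return a [similarity_matrix()].
#' @export
rbf_similarity <- function(F, bandwidth = "median") {
  m <- unclass(F)
  sq <- rowSums(m^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * m %*% t(m), 0)
  if (identical(bandwidth, "median")) {
    off <- d2[upper.tri(d2)]
    bandwidth <- stats::median(off)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  S <- exp(-d2 / bandwidth)
  diag(S) <- 1
  similarity_matrix(S, ids = rownames(m))
}
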