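# Target partition: TWSNI (targets with smaller numbers of interactions,
# count <= tau) vs TWLNI (larger, count > tau). The boundary is <= on the
# small side so that tau = 1 makes TWSNI exactly the degree-<=1 targets,
# the regime where nearest-profile transfer is the intended predictor.

#' Per-target interaction counts
#'
#' @param Y an [interaction_matrix()].
#' @return named integer vector of column sums of `Y`.
#' @export
count_target_interactions <- function(Y) {
  counts <- colSums(Y)
  storage.mode(counts) <- "integer"
  counts
}

#' Split targets into TWLNI and TWSNI by interaction count
#'
#' Targets with more than `tau` known interactions form TWLNI and are
#' predicted per-target; the rest (count `<= tau`) form TWSNI and are
#' predicted by similarity transfer. By default counts come from the full
#' interaction matrix (the partition is a preprocessing step fixed before
#' cross-validation); pass a training-fold submatrix to partition per fold.
#'
#' @param Y an [interaction_matrix()].
#' @param tau non-negative integer threshold.
#' @return a `target_partition` list with `tau`, `twlni_ids`, `twsni_ids`,
#'   `counts`.
#' @export
partition_targets <- function(Y, tau) {
  stopifnot(length(tau) == 1L, tau >= 0)
  counts <- count_target_interactions(Y)
  structure(list(tau = as.integer(tau),
                 twlni_ids = names(counts)[counts > tau],
                 twsni_ids = names(counts)[counts <= tau],
                 counts = counts),
            class = "target_partition")
}

#' @export
print.target_partition <- function(x, ...) {
  cat(sprintf("<target_partition tau=%d> TWLNI: %d targets, TWSNI: %d targets\n",
              x$tau, length(x$twlni_ids), length(x$twsni_ids)))
  invisible(x)
}
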