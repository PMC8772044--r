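# Reading/writing of the external table formats:
#   * pair list:     two-column delimited file, no header, one pair per line
#   * dense matrix:  delimited file, header row of column ids, first column
#                    holds row ids (interaction / similarity / feature)
# Identifiers are case-sensitive opaque strings; tab is the default delimiter.

#' Read a drug-target pair list into an interaction matrix
#'
#' @param path two-column delimited file, no header, one interacting pair per
#'   line.
#' @param all_drugs,all_targets optional identifier universes. When supplied,
#'   a pair referencing an unknown identifier is a hard error; when `NULL` the
#'   universe is the sorted union of identifiers seen in the file.
#' @param order column order in the file: `"drug_target"` or `"target_drug"`.
#'   There is no sniffing; the caller must know the dialect.
#' @param sep field delimiter, tab by default.
#' @return an [interaction_matrix()] with 1 at every listed pair.
#'   Duplicate pairs are accepted idempotently with a warning.
#' @export
read_pair_list <- function(path, all_drugs = NULL, all_targets = NULL,
                           order = c("drug_target", "target_drug"),
                           sep = "\t") {
  order <- match.arg(order)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) {
    stop("pair list must have exactly two columns, found ", ncol(tab), call. = FALSE)
  }
  drugs <- if (order == "drug_target") tab[[1L]] else tab[[2L]]
  targets <- if (order == "drug_target") tab[[2L]] else tab[[1L]]
  dup <- duplicated(paste(drugs, targets, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) in ", path, "; kept once", call. = FALSE)
  }
  if (is.null(all_drugs)) all_drugs <- sort(unique(drugs))
  if (is.null(all_targets)) all_targets <- sort(unique(targets))
  unknown_d <- setdiff(drugs, all_drugs)
  unknown_t <- setdiff(targets, all_targets)
  if (length(unknown_d) || length(unknown_t)) {
    stop("pair list references identifiers outside the supplied universe: ",
         paste(utils::head(c(unknown_d, unknown_t), 10L), collapse = ", "),
         call. = FALSE)
  }
  Y <- matrix(0, length(all_drugs), length(all_targets),
              dimnames = list(all_drugs, all_targets))
  Y[cbind(drugs, targets)] <- 1
  interaction_matrix(Y)
}

#' Write an interaction matrix as a pair list
#'
#' @param Y an [interaction_matrix()].
#' @param path output file.
#' @param order,sep dialect, as in [read_pair_list()].
#' @export
write_pair_list <- function(Y, path, order = c("drug_target", "target_drug"),
                            sep = "\t") {
  order <- match.arg(order)
  idx <- which(Y == 1, arr.ind = TRUE)
  d <- rownames(Y)[idx[, 1L]]
  t <- colnames(Y)[idx[, 2L]]
  tab <- if (order == "drug_target") data.frame(d, t) else data.frame(t, d)
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense labelled matrix
#'
#' @param path delimited file with a header row of column identifiers and a
#'   first column of row identifiers.
#' @param kind one of `"interaction"`, `"similarity"`, `"feature"`; selects
#'   the validator applied to the parsed table. For `"feature"`, the
#'   `feature_kind` argument distinguishes binary drug fingerprints from
#'   real-valued target descriptors.
#' @param feature_kind `"drug"` or `"target"`; only used when
#'   `kind = "feature"`.
#' @param sep field delimiter, tab by default.
#' @return a validated [interaction_matrix()], [similarity_matrix()] or
#'   [feature_matrix()]. A validation failure reports every violated
#'   invariant, not only the first.
#' @export
read_dense_matrix <- function(path, kind = c("interaction", "similarity", "feature"),
                              feature_kind = c("drug", "target"), sep = "\t") {
  kind <- match.arg(kind)
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "", row.names = 1L,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  switch(kind,
         interaction = interaction_matrix(m),
         similarity = similarity_matrix(m),
         feature = feature_matrix(m, kind = feature_kind))
}

#' Write a dense labelled matrix
#'
#' Inverse of [read_dense_matrix()]: header row of column identifiers, first
#' column of row identifiers, full numeric precision.
#'
#' @param m a matrix with dimnames.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_dense_matrix <- function(m, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = sep), con)
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

#' Summary statistics of an interaction matrix
#'
#' Counts of drugs, targets and known interactions, plus the interaction
#' density as a percentage of the drug-target pair space. The internal value
#' is never rounded; `digits` only affects the `density_display` string, so
#' that the sparsest benchmark sets can be echoed at the precision they are
#' conventionally reported at.
#'
#' @param Y an [interaction_matrix()].
#' @param digits decimals for the display string (default 2).
#' @return a list with `n_drugs`, `n_targets`, `n_interactions`,
#'   `density_percent`, `density_display`.
#' @export
dataset_summary <- function(Y, digits = 2L) {
  if (nrow(Y) == 0L || ncol(Y) == 0L) {
    stop("interaction matrix has zero drugs or zero targets", call. = FALSE)
  }
  n_int <- sum(Y)
  density <- 100 * n_int / (nrow(Y) * ncol(Y))
  list(n_drugs = nrow(Y), n_targets = ncol(Y), n_interactions = n_int,
       density_percent = density,
       density_display = sprintf("%.*f%%", digits, density))
}

#' Share of interactions held by the most-connected targets
#'
#' Sorts targets by interaction count (descending) and returns the fraction
#' of all interactions carried by the top `ceiling(top_fraction * n_targets)`
#' targets. In public chemogenomic benchmarks this concentration is strong:
#' roughly half or more of all interactions sit on the top 20% of targets.
#'
#' @param Y an [interaction_matrix()] with at least one interaction.
#' @param top_fraction proportion of targets to take, in (0, 1].
#' @return proportion of interactions in \[0, 1\].
#' @export
degree_concentration <- function(Y, top_fraction) {
  stopifnot(length(top_fraction) == 1L, top_fraction > 0, top_fraction <= 1)
  total <- sum(Y)
  if (total == 0) stop("no interactions present", call. = FALSE)
  counts <- sort(colSums(Y), decreasing = TRUE)
  k <- ceiling(top_fraction * length(counts))
  sum(counts[seq_len(k)]) / total
}
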