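# Typed matrix containers. All three are plain numeric matrices with row and
# column dimnames plus a class tag; validation happens at construction and at
# every I/O boundary. Subsetting intentionally drops to a plain matrix:
# internal code works on base matrices, identifiers travel in dimnames.

#' Construct a validated binary drug x target interaction matrix
#'
#' The central data object: `Y[i, j] = 1` when drug `i` is known to interact
#' with target `j`, 0 otherwise (an unobserved pair is indistinguishable from
#' a true negative, as usual in chemogenomic data).
#'
#' @param values numeric matrix with entries in \{0, 1\}.
#' @param drug_ids,target_ids identifier character vectors; default to the
#'   dimnames of `values`.
#' @return the matrix with dimnames set and class `"interaction_matrix"`.
#' @export
interaction_matrix <- function(values, drug_ids = rownames(values),
                               target_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_ids, target_ids)
  problems <- validate_interaction_matrix(values)
  if (length(problems)) {
    stop("invalid interaction matrix:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(values, class = c("interaction_matrix", "matrix", "array"))
}

validate_interaction_matrix <- function(values) {
  problems <- validate_ids(values)
  bad <- which(!(values %in% c(0, 1)) | is.na(values))
  if (length(bad)) {
    coords <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(values))
    problems <- c(problems, sprintf(
      "%d cell(s) not in {0,1}; first at (row %s, col %s) = %s",
      length(bad), coords[1, 1], coords[1, 2], values[bad[1]]))
  }
  problems
}

#' Construct a validated feature matrix for drugs or targets
#'
#' Drug features are substructure-fingerprint bits (binary, default dimension
#' 1024); target features are real-valued protein descriptors (default
#' dimension 1437).
#'
#' @param values numeric matrix, rows are drugs or targets.
#' @param kind `"drug"` (binary entries enforced) or `"target"` (real-valued).
#' @param row_ids,feature_names identifiers; default to dimnames.
#' @return the matrix with class `"feature_matrix"` and a `kind` attribute.
#' @export
feature_matrix <- function(values, kind = c("drug", "target"),
                           row_ids = rownames(values),
                           feature_names = colnames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(values)))
  }
  dimnames(values) <- list(row_ids, feature_names)
  problems <- validate_feature_matrix(values, kind)
  if (length(problems)) {
    stop("invalid ", kind, " feature matrix:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(values, kind = kind, class = c("feature_matrix", "matrix", "array"))
}

validate_feature_matrix <- function(values, kind) {
  problems <- validate_ids(values)
  if (anyNA(values)) problems <- c(problems, "missing values present")
  if (kind == "drug" && !all(values %in% c(0, 1), na.rm = TRUE)) {
    problems <- c(problems, "drug fingerprint entries must be 0/1 bits")
  }
  problems
}

#' Construct a validated square similarity matrix
#'
#' Symmetric, entries in \[0, 1\], unit diagonal (each within 1e-9), over
#' either the drug or the target identifier set.
#'
#' @param values square numeric matrix.
#' @param ids identifiers for rows and columns; defaults to rownames.
#' @return the matrix with class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, ids)
  problems <- validate_similarity_matrix(values)
  if (length(problems)) {
    stop("invalid similarity matrix:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(values, class = c("similarity_matrix", "matrix", "array"))
}

validate_similarity_matrix <- function(values, tol = 1e-9) {
  problems <- character()
  if (nrow(values) != ncol(values)) {
    problems <- c(problems, sprintf("not square: %d x %d", nrow(values), ncol(values)))
    return(problems)
  }
  problems <- c(problems, validate_ids(values))
  if (anyNA(values)) problems <- c(problems, "missing values present")
  asym <- abs(values - t(values))
  if (any(asym > tol, na.rm = TRUE)) {
    w <- arrayInd(which.max(asym), dim(values))
    problems <- c(problems, sprintf(
      "asymmetric beyond tolerance %g: S[%d,%d]=%g vs S[%d,%d]=%g",
      tol, w[1], w[2], values[w[1], w[2]], w[2], w[1], values[w[2], w[1]]))
  }
  if (any(values < -tol | values > 1 + tol, na.rm = TRUE)) {
    problems <- c(problems, "entries outside [0, 1]")
  }
  if (nrow(values) > 0 && any(abs(diag(values) - 1) > tol, na.rm = TRUE)) {
    problems <- c(problems, "diagonal entries not all equal to 1")
  }
  problems
}

validate_ids <- function(values) {
  problems <- character()
  rid <- rownames(values)
  cid <- colnames(values)
  # a zero-extent dimension stores NULL dimnames; that is not a violation
  if ((is.null(rid) && nrow(values) > 0) || (is.null(cid) && ncol(values) > 0)) {
    problems <- c(problems, "row and column identifiers are required")
    return(problems)
  }
  if (anyDuplicated(rid)) problems <- c(problems, "duplicated row identifiers")
  if (anyDuplicated(cid)) problems <- c(problems, "duplicated column identifiers")
  problems
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d drugs x %d targets, %d interactions (%.3g%% dense)\n",
              nrow(x), ncol(x), sum(x),
              if (length(x)) 100 * sum(x) / length(x) else 0))
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix kind=%s> %d rows x %d features\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, off-diagonal range [%.3g, %.3g]\n",
              nrow(x), ncol(x),
              if (nrow(x) > 1) min(x[upper.tri(x)]) else NA_real_,
              if (nrow(x) > 1) max(x[upper.tri(x)]) else NA_real_))
  invisible(x)
}

#' Score matrix over (drug, target) cells
#'
#' Holds real-valued prediction scores for test-drug rows; `mask` marks which
#' cells were actually scored (a per-target model can be unfittable in a fold,
#' leaving its column unscored).
#'
#' @param scores numeric matrix (drugs x targets) with dimnames.
#' @param mask logical matrix of the same shape; defaults to all-scored.
#' @return a `score_matrix` object.
#' @export
score_matrix <- function(scores, mask = NULL) {
  scores <- as.matrix(scores)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(scores), ncol(scores))
  mask <- as.matrix(mask)
  stopifnot(identical(dim(scores), dim(mask)))
  if ((is.null(rownames(scores)) && nrow(scores) > 0) ||
      (is.null(colnames(scores)) && ncol(scores) > 0)) {
    stop("score matrix requires drug and target identifiers", call. = FALSE)
  }
  if (any(mask & (!is.finite(scores) | scores < 0 | scores > 1))) {
    stop("scored cells must be finite and in [0, 1]", call. = FALSE)
  }
  dimnames(mask) <- dimnames(scores)
  structure(list(scores = scores, mask = mask,
                 drug_ids = rownames(scores), target_ids = colnames(scores)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d drugs x %d targets, %d/%d cells scored\n",
              length(x$drug_ids), length(x$target_ids),
              sum(x$mask), length(x$mask)))
  invisible(x)
}
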