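#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t readMM writeMM
NULL

.FAMILY_LEVELS <- c("ZERO", "POS_HALF_NORMAL", "NEG_HALF_NORMAL", "FREE_NORMAL")

#' Signed TF-target prior network
#'
#' A sparse signed adjacency matrix over genes (rows) and transcription
#' factors (columns). Entries are -1 (inhibition), 0 (no known edge) or
#' +1 (activation). Edges restrict which entries of the regulatory weight
#' matrix may be nonzero: a zero prior entry fixes the weight at zero.
#'
#' @slot signs a \code{\link[Matrix]{dgCMatrix-class}} with entries in
#'   \{-1, 0, +1\}; rows are target genes, columns are TFs, both named.
#' @export
setClass("PriorNetwork", representation(signs = "dgCMatrix"))

setValidity("PriorNetwork", function(object) {
  s <- object@signs
  msgs <- character()
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msgs <- c(msgs, "signs must have gene row names and TF column names")
  else {
    if (anyDuplicated(rownames(s))) msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(s))) msgs <- c(msgs, "duplicate TF ids")
  }
  if (length(s@x) && !all(s@x %in% c(-1, 1)))
    msgs <- c(msgs, "nonzero entries must be -1 or +1")
  if (any(Matrix::colSums(s != 0) == 0))
    msgs <- c(msgs, "every TF column must have at least one edge")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PriorNetwork from a signed adjacency matrix
#'
#' TF columns left without any edge are dropped with a warning rather than
#' rejected, mirroring how curated priors are pruned after gene filtering.
#'
#' @param signs numeric/sparse matrix, genes x TFs, entries in \{-1, 0, +1\},
#'   with row and column names.
#' @return a \linkS4class{PriorNetwork}.
#' @export
PriorNetwork <- function(signs) {
  s <- as(as(Matrix(signs, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  s <- drop0(s)
  if (length(s@x) && !all(s@x %in% c(-1, 1)))
    stop("prior signs must lie in {-1, 0, +1}")
  empty <- Matrix::colSums(s != 0) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d TF(s) with no edges: %s", sum(empty),
                    paste(colnames(s)[empty], collapse = ", ")))
    s <- s[, !empty, drop = FALSE]
  }
  if (ncol(s) == 0L) stop("prior network has no TFs with edges")
  new("PriorNetwork", signs = s)
}

#' @importFrom Matrix drop0
NULL

#' Per-edge prior-distribution assignments
#'
#' For every (gene, TF) pair, records which prior family the edge weight
#' receives: \code{ZERO} (no prior edge, weight fixed at zero),
#' \code{POS_HALF_NORMAL} / \code{NEG_HALF_NORMAL} (hard sign constraint,
#' assigned when the prior edge sign agrees with the shrinkage partial
#' correlation between TF and target expression), or \code{FREE_NORMAL}
#' (sign left to be learned).
#'
#' @slot family integer matrix genes x TFs; codes index into
#'   \code{ZERO, POS_HALF_NORMAL, NEG_HALF_NORMAL, FREE_NORMAL} (0-3).
#' @slot pcor numeric matrix of TF-target partial correlations; NA where
#'   undefined (no prior edge, or the TF's own gene is unmeasured).
#' @slot priorSigns the signed prior adjacency the table was derived from.
#' @slot threshold the |pcor| threshold below which sign evidence is ignored.
#' @export
setClass("ConstraintTable",
         representation(family = "matrix", pcor = "matrix",
                        priorSigns = "dgCMatrix", threshold = "numeric"))

setValidity("ConstraintTable", function(object) {
  fam <- object@family
  msgs <- character()
  if (!is.integer(fam[1])) msgs <- c(msgs, "family codes must be integer")
  if (!all(fam %in% 0:3)) msgs <- c(msgs, "family codes must be 0..3")
  if (!identical(dim(fam), dim(object@pcor)))
    msgs <- c(msgs, "family and pcor dimensions differ")
  sg <- as.matrix(object@priorSigns)
  if (!identical(dim(fam), dim(sg)))
    msgs <- c(msgs, "family and priorSigns dimensions differ")
  if (any((fam == 0L) != (sg == 0)))
    msgs <- c(msgs, "family must be ZERO exactly where the prior sign is 0")
  if (any(fam == 1L & sg != 1) || any(fam == 2L & sg != -1))
    msgs <- c(msgs, "half-normal families must match the prior sign")
  if (length(msgs)) msgs else TRUE
})

#' Posterior fit of the factorization model
#'
#' Posterior means and standard deviations of the regulatory weights W
#' (genes x TFs) and the non-negative TF activities Z (TFs x samples),
#' posterior mean edge variances and noise variance, the ELBO trace
#' (for VI fits) and full provenance (method, seed, configuration,
#' hyperparameters, constraint family counts).
#'
#' @slot W_mean,W_sd numeric matrices, genes x TFs.
#' @slot Z_mean,Z_sd numeric matrices, TFs x samples; \code{Z_mean >= 0}.
#' @slot alpha_mean numeric vector of posterior mean edge variances, one per
#'   nonzero prior edge, named \code{"tf->gene"}.
#' @slot sigma_eps2_mean posterior mean noise variance (scalar).
#' @slot elbo_trace numeric; smoothed ELBO values recorded during VI.
#' @slot method "VI" or "MCMC".
#' @slot config list; the fit configuration used (includes the seed).
#' @slot hyper list; hyperparameter values used.
#' @slot constraint_counts named integer; edges per prior family.
#' @slot converged logical; \code{iterations} integer.
#' @export
setClass("TigerFit",
         representation(W_mean = "matrix", W_sd = "matrix",
                        Z_mean = "matrix", Z_sd = "matrix",
                        alpha_mean = "numeric", sigma_eps2_mean = "numeric",
                        elbo_trace = "numeric", method = "character",
                        config = "list", hyper = "list",
                        constraint_counts = "integer",
                        converged = "logical", iterations = "integer"))

setValidity("TigerFit", function(object) {
  msgs <- character()
  if (any(object@Z_mean < 0)) msgs <- c(msgs, "Z_mean must be non-negative")
  if (!identical(dim(object@W_mean), dim(object@W_sd)))
    msgs <- c(msgs, "W_mean/W_sd dimensions differ")
  if (ncol(object@W_mean) != nrow(object@Z_mean))
    msgs <- c(msgs, "W and Z TF dimensions differ")
  if (length(msgs)) msgs else TRUE
})

#' Within-sample TF activity ranks
#'
#' @slot ranks numeric matrix TFs x samples; each column is a permutation of
#'   1..h up to average-rank ties (columns sum to h(h+1)/2).
#' @slot direction "LOWEST_FIRST" (rank 1 = lowest activity; knockout
#'   convention) or "HIGHEST_FIRST" (rank 1 = most active TF).
#' @slot standardized whether activities were per-TF standardized first.
#' @export
setClass("TFARankTable",
         representation(ranks = "matrix", direction = "character",
                        standardized = "logical"))

setValidity("TFARankTable", function(object) {
  h <- nrow(object@ranks)
  msgs <- character()
  if (!object@direction %in% c("LOWEST_FIRST", "HIGHEST_FIRST"))
    msgs <- c(msgs, "unknown direction")
  if (h > 0 &&
      any(abs(colSums(object@ranks) - h * (h + 1) / 2) > 1e-8))
    msgs <- c(msgs, "each column must sum to h(h+1)/2")
  if (length(msgs)) msgs else TRUE
})
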