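#' Standardize TF activities across samples
#'
#' Raw activities are non-negative and their scale trades off against the
#' regulon weight scale, so they are not comparable across TFs. Each TF row
#' is z-scored across samples (n-1 denominator); rows with zero variance are
#' set to zero and listed in \code{attr(, "flagged")}.
#'
#' @param z numeric matrix TFs x samples, n >= 2.
#' @return standardized matrix of the same shape.
#' @export
standardizeTFA <- function(z) {
  if (ncol(z) < 2L) stop("at least 2 samples are required")
  sds <- apply(z, 1, stats::sd)
  flagged <- rownames(z)[sds == 0]
  out <- (z - rowMeans(z)) / ifelse(sds == 0, 1, sds)
  out[sds == 0, ] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Rank TFs within each sample
#'
#' Per-column ranking with average ranks for ties. With
#' \code{"LOWEST_FIRST"} the TF with the lowest activity gets rank 1 (the
#' knockout convention: a knocked-out TF should be least active); with
#' \code{"HIGHEST_FIRST"} the most active TF gets rank 1.
#'
#' @param z numeric matrix TFs x samples (typically standardized, see
#'   \code{\link{standardizeTFA}}).
#' @param direction "LOWEST_FIRST" or "HIGHEST_FIRST".
#' @param standardized flag recorded in the result (set by callers that
#'   standardized first).
#' @return a \linkS4class{TFARankTable}.
#' @export
rankTFA <- function(z, direction = c("LOWEST_FIRST", "HIGHEST_FIRST"),
                    standardized = FALSE) {
  direction <- match.arg(direction)
  r <- apply(z, 2, function(col)
    if (direction == "LOWEST_FIRST") rank(col) else rank(-col))
  r <- matrix(r, nrow = nrow(z), dimnames = dimnames(z))
  new("TFARankTable", ranks = r, direction = direction,
      standardized = standardized)
}

#' @rdname rankTFA
#' @param x a \linkS4class{TFARankTable}.
#' @return \code{tfaRanks} returns the numeric rank matrix.
#' @export
tfaRanks <- function(x) x@ranks

#' L1-normalize regulon weights
#'
#' Divides each TF column of the weight matrix by its L1 norm so that
#' \eqn{\sum_j |W_{ij}| = 1} per TF, the normalization under which regulon
#' quality scores are defined. Signs are preserved; idempotent.
#'
#' @param W numeric matrix genes x TFs.
#' @return the column-normalized matrix.
#' @export
normalizeRegulons <- function(W) {
  l1 <- colSums(abs(W))
  if (any(l1 == 0))
    stop("all-zero regulon for TF(s): ",
         paste(colnames(W)[l1 == 0], collapse = ", "))
  sweep(W, 2, l1, "/")
}

#' Gene in-degree from the inferred network
#'
#' The in-degree of a gene is the sum of the absolute weights of all edges
#' targeting it. Genes are returned in descending in-degree order with a
#' lexicographic tie-break, so heavily regulated genes come first.
#'
#' @param W numeric matrix genes x TFs.
#' @return data.frame with columns \code{gene} and \code{in_degree}.
#' @export
geneInDegree <- function(W) {
  d <- rowSums(abs(W))
  ord <- order(-d, rownames(W))
  data.frame(gene = rownames(W)[ord], in_degree = unname(d[ord]),
             stringsAsFactors = FALSE)
}
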