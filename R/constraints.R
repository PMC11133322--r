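#' Shrinkage-regularized correlation matrix
#'
#' Correlation matrix across genes (rows of \code{x}) shrunk toward the
#' identity, \eqn{R^* = (1-\lambda) R + \lambda I}, with the analytic
#' optimal intensity \eqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) /
#' \sum_{i \ne j} r_{ij}^2} (clipped to [0, 1]). This keeps the estimate
#' positive definite and invertible when genes outnumber samples, which is
#' the usual regime for expression data.
#'
#' @param x numeric matrix genes x samples, n >= 3.
#' @return the shrunk correlation matrix, with \code{attr(, "lambda")}.
#' @export
shrinkageCorrelation <- function(x) {
  n <- ncol(x)
  if (n < 3L) stop("at least 3 samples are required")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("constant gene rows: ",
                          paste(utils::head(rownames(x)[sds == 0], 5),
                                collapse = ", "))
  xs <- (x - rowMeans(x)) / sds
  r <- tcrossprod(xs) / (n - 1)
  # var of r_ij from the empirical variance of the centered cross-products
  w2 <- tcrossprod(xs^2)                      # sum_k x_ki^2 x_kj^2
  wbar <- r * (n - 1) / n
  var_r <- n / (n - 1)^3 * (w2 - n * wbar^2)
  od <- upper.tri(r)
  denom <- sum(r[od]^2)
  lambda <- if (denom > 0) sum(var_r[od]) / denom else 1
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  attr(rs, "lambda") <- lambda
  rs
}

#' TF-target partial correlations from a shrinkage estimator
#'
#' Partial correlation between each (TF gene, target gene) pair given all
#' other genes in the conditioning set, read off the inverse of the shrunk
#' correlation matrix: \eqn{\rho_{ij\cdot} = -\Omega_{ij} /
#' \sqrt{\Omega_{ii}\Omega_{jj}}} with \eqn{\Omega = (R^*)^{-1}}. The
#' conditioning set is all genes of \code{x}; above 2000 genes it is capped
#' to the union of genes appearing in \code{pairs} for tractability.
#'
#' @param x numeric expression matrix genes x samples (n >= 3).
#' @param pairs data.frame with columns \code{tf} and \code{gene}, both
#'   referring to rows of \code{x}.
#' @return numeric vector of partial correlations in [-1, 1], one per pair,
#'   with \code{attr(, "lambda")}.
#' @export
shrinkagePartialCorrelation <- function(x, pairs) {
  stopifnot(is.data.frame(pairs), all(c("tf", "gene") %in% names(pairs)))
  ids <- unique(c(pairs$tf, pairs$gene))
  unknown <- setdiff(ids, rownames(x))
  if (length(unknown))
    stop("pair references unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  genes <- if (nrow(x) > 2000L) {
    rownames(x)[rownames(x) %in% ids]
  } else rownames(x)
  rs <- shrinkageCorrelation(x[genes, , drop = FALSE])
  omega <- chol2inv(chol(rs))
  d <- sqrt(diag(omega))
  i <- match(pairs$tf, genes)
  j <- match(pairs$gene, genes)
  pc <- -omega[cbind(i, j)] / (d[i] * d[j])
  pc[i == j] <- 1
  pc <- pmin(1, pmax(-1, pc))
  attr(pc, "lambda") <- attr(rs, "lambda")
  pc
}

#' Assign per-edge prior families from sign agreement
#'
#' Compares each prior edge sign against the partial correlation between the
#' TF's own expression and the target's expression. Agreement yields a hard
#' half-normal sign constraint (\code{POS_HALF_NORMAL} /
#' \code{NEG_HALF_NORMAL}); disagreement, absent or below-threshold evidence
#' leaves the edge as a sign-free \code{FREE_NORMAL}; entries without a
#' prior edge are \code{ZERO} (the weight is fixed at zero). A TF whose own
#' gene is not a row of \code{x} has no expression proxy, so all of its
#' edges stay \code{FREE_NORMAL}.
#'
#' @param prior a \linkS4class{PriorNetwork} (aligned with \code{x}).
#' @param x expression matrix genes x samples; may be omitted when
#'   \code{pcor} is supplied.
#' @param pcor optional precomputed partial-correlation matrix
#'   (genes x TFs, NA = undefined); when missing it is computed with
#'   \code{\link{shrinkagePartialCorrelation}}.
#' @param threshold evidence threshold: edges with \eqn{|pcor| \le}
#'   \code{threshold} get no sign constraint. Default 0, i.e. any nonzero
#'   agreement counts (a zero partial correlation still yields
#'   \code{FREE_NORMAL}).
#' @return a \linkS4class{ConstraintTable}.
#' @export
assignConstraints <- function(prior, x = NULL, pcor = NULL, threshold = 0) {
  stopifnot(threshold >= 0)
  s <- as.matrix(priorSigns(prior))
  g <- nrow(s); h <- ncol(s)
  if (is.null(pcor)) {
    if (is.null(x)) stop("supply either an expression matrix or pcor")
    pcor <- matrix(NA_real_, g, h, dimnames = dimnames(s))
    st <- as(priorSigns(prior), "TsparseMatrix")
    tf <- colnames(s)[st@j + 1L]
    gene <- rownames(s)[st@i + 1L]
    measured <- tf %in% rownames(x)
    if (any(measured)) {
      pr <- data.frame(tf = tf[measured], gene = gene[measured])
      pc <- shrinkagePartialCorrelation(x, pr)
      pcor[cbind(st@i + 1L, st@j + 1L)[measured, , drop = FALSE]] <- pc
    }
  } else {
    pcor <- as.matrix(pcor)
    if (!identical(dim(pcor), dim(s)))
      stop("pcor must be a genes x TFs matrix matching the prior")
  }
  fam <- matrix(0L, g, h, dimnames = dimnames(s))
  edge <- s != 0
  fam[edge] <- 3L  # FREE_NORMAL unless promoted below
  agree_pos <- edge & s == 1 & !is.na(pcor) & pcor > threshold
  agree_neg <- edge & s == -1 & !is.na(pcor) & pcor < -threshold
  fam[agree_pos] <- 1L
  fam[agree_neg] <- 2L
  pcor[!edge] <- NA_real_
  ct <- new("ConstraintTable", family = fam, pcor = pcor,
            priorSigns = priorSigns(prior), threshold = threshold)
  validObject(ct)
  ct
}
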