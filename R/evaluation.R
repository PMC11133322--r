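#' Ascending rank percentiles
#'
#' Converts scores to \code{rank/k} with average ranks for ties, so the
#' largest score maps to 1 and values lie in (0, 1].
#'
#' @param scores numeric vector of finite values, length >= 1.
#' @return numeric vector of percentiles.
#' @export
rankPercentile <- function(scores) {
  if (length(scores) == 0L) stop("empty score list")
  if (any(!is.finite(scores))) stop("scores must be finite")
  rank(scores) / length(scores)
}

#' Regulon quality score
#'
#' Inner product between L1-normalized absolute edge weights and external
#' per-edge evidence percentiles: \eqn{QS_i = \sum_j |W_{ij}| C_{ij}} with
#' \eqn{\sum_j |W_{ij}| = 1}. With uniform weights (a prior network) this is
#' the arithmetic mean of the evidence scores; a model that up-weights
#' well-supported edges raises it.
#'
#' @param weights per-target edge weights (signs are ignored), not all zero.
#' @param chip_pct per-target evidence percentiles in (0, 1], same length.
#' @return the quality score, in [0, 1] when \code{chip_pct} are percentiles.
#' @export
regulonQS <- function(weights, chip_pct) {
  if (length(weights) != length(chip_pct))
    stop("weights and scores differ in length")
  if (length(weights) == 0L) stop("empty regulon")
  w <- abs(weights)
  if (sum(w) == 0) stop("all-zero weights")
  sum(w / sum(w) * chip_pct)
}

#' Regulon quality report for a fitted network
#'
#' For each TF with external evidence, computes the prior QS (uniform
#' weights over its scored edges, i.e. the arithmetic mean of the evidence
#' percentiles), the posterior QS under the fitted weights, and the relative
#' improvement (posterior - prior)/prior. Evidence scores are converted to
#' rank percentiles per TF.
#'
#' @param W fitted weight matrix genes x TFs.
#' @param scores data.frame with columns tf, gene, score (see
#'   \code{\link{loadEdgeScores}}).
#' @return data.frame with columns tf, prior_qs, posterior_qs, improvement.
#' @export
regulonQSReport <- function(W, scores) {
  scores <- scores[scores$tf %in% colnames(W) &
                     scores$gene %in% rownames(W), , drop = FALSE]
  if (nrow(scores) == 0L) stop("no scored edges overlap the network")
  out <- lapply(split(scores, scores$tf), function(df) {
    pct <- rankPercentile(df$score)
    w <- W[cbind(match(df$gene, rownames(W)), match(df$tf, colnames(W)))]
    if (sum(abs(w)) == 0) return(NULL)
    prior <- mean(pct)
    post <- regulonQS(w, pct)
    data.frame(tf = df$tf[1], prior_qs = prior, posterior_qs = post,
               improvement = (post - prior) / prior,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$tf), , drop = FALSE]
}

#' Rank-biased overlap of two rankings
#'
#' Extrapolated rank-biased overlap with persistence \code{p}: per-depth
#' agreement \eqn{A_d = |top_d(a) \cap top_d(b)|/d} combined with geometric
#' weights \eqn{(1-p)p^{d-1}} and extrapolated beyond the evaluated depth,
#' so the score lies in [0, 1] and emphasizes the top of the lists. Lists
#' may have different lengths; the measure is symmetric.
#'
#' @param list_a,list_b character/atomic vectors of ids, duplicate-free.
#' @param p persistence in (0, 1); larger values weight deeper ranks more.
#'   Default 0.98 keeps strong top-weighting.
#' @return RBO score in [0, 1].
#' @export
rbo <- function(list_a, list_b, p = 0.98) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    stop("ranked lists must be duplicate-free")
  if (length(list_a) == 0L || length(list_b) == 0L)
    stop("ranked lists must be non-empty")
  if (length(list_a) < length(list_b)) {
    short <- list_a; long <- list_b
  } else {
    short <- list_b; long <- list_a
  }
  s <- length(short); l <- length(long)
  d <- seq_len(l)
  x_d <- vapply(d, function(k)
    length(intersect(short[seq_len(min(k, s))], long[seq_len(k)])),
    numeric(1))
  x_s <- x_d[s]; x_l <- x_d[l]
  sum1 <- sum(x_d / d * p^d)
  sum2 <- if (l > s) sum(x_s * (d[(s + 1):l] - s) / (s * d[(s + 1):l]) *
                           p^(d[(s + 1):l])) else 0
  (1 - p) / p * (sum1 + sum2) + ((x_l - x_s) / l + x_s / s) * p^l
}

#' Edge-sign accuracy against gold-standard signs
#'
#' Fraction of the scoped edges whose estimated weight sign matches the
#' gold-standard sign. An estimated sign of exactly zero counts as
#' incorrect (no call is a wrong call).
#'
#' @param W estimated weight matrix genes x TFs (or a sign matrix).
#' @param gold gold-standard signs: a sparse/dense genes x TFs matrix with
#'   entries in \{-1, 0, +1\} (gene/TF named).
#' @param edges the edge subset to score: data.frame with columns tf, gene;
#'   default all nonzero gold edges present in \code{W}.
#' @return accuracy in [0, 1].
#' @export
edgeSignAccuracy <- function(W, gold, edges = NULL) {
  gold <- as.matrix(gold)
  if (is.null(edges)) {
    idx <- which(gold != 0, arr.ind = TRUE)
    edges <- data.frame(tf = colnames(gold)[idx[, 2]],
                        gene = rownames(gold)[idx[, 1]])
    edges <- edges[edges$tf %in% colnames(W) & edges$gene %in% rownames(W), ]
  }
  if (nrow(edges) == 0L) stop("empty edge scope")
  gs <- gold[cbind(match(edges$gene, rownames(gold)),
                   match(edges$tf, colnames(gold)))]
  if (any(gs == 0)) stop("gold signs must be -1 or +1 on the scored edges")
  est <- sign(W[cbind(match(edges$gene, rownames(W)),
                      match(edges$tf, colnames(W)))])
  mean(est == gs)
}

#' Knockout identification metrics
#'
#' Given within-sample activity ranks (lowest activity = rank 1) and a map
#' from knockout samples to their knocked-out TF, reports the rank of the
#' knocked-out TF in its own sample and whether it counts as a success
#' (rank at most \code{top}; default 10).
#'
#' @param ranks a \linkS4class{TFARankTable} with direction
#'   \code{"LOWEST_FIRST"}.
#' @param ko_map named character vector: names are sample ids, values the
#'   knocked-out TF ids.
#' @param top success cutoff on the rank.
#' @return data.frame with columns sample, ko_tf, rank, success;
#'   \code{attr(, "n_success")} and \code{attr(, "success_rate")} summarize.
#' @export
knockoutMetrics <- function(ranks, ko_map, top = 10) {
  if (ranks@direction != "LOWEST_FIRST")
    stop("knockout metrics require LOWEST_FIRST ranks")
  r <- ranks@ranks
  if (!all(names(ko_map) %in% colnames(r)))
    stop("unknown sample(s): ",
         paste(setdiff(names(ko_map), colnames(r)), collapse = ", "))
  if (!all(ko_map %in% rownames(r)))
    stop("unknown TF(s): ",
         paste(setdiff(ko_map, rownames(r)), collapse = ", "))
  rk <- r[cbind(match(ko_map, rownames(r)), match(names(ko_map), colnames(r)))]
  out <- data.frame(sample = names(ko_map), ko_tf = unname(ko_map),
                    rank = unname(rk), success = unname(rk) <= top,
                    stringsAsFactors = FALSE)
  attr(out, "n_success") <- sum(out$success)
  attr(out, "success_rate") <- mean(out$success)
  out
}

#' Sign-aware mean-z baseline activity
#'
#' A simple regulon-average comparator: the activity of a TF in a sample is
#' the mean over its regulon of (edge sign) x (z-scored target expression).
#' Used as the plumbing baseline in comparative simulations.
#'
#' @param x z-scored expression matrix genes x samples (aligned).
#' @param prior a \linkS4class{PriorNetwork}.
#' @return numeric matrix TFs x samples; TFs with an empty regulon get NA
#'   rows and are listed in \code{attr(, "empty")}.
#' @export
baselineSignedMean <- function(x, prior) {
  s <- priorSigns(prior)
  common <- intersect(rownames(s), rownames(x))
  s <- s[common, , drop = FALSE]
  sizes <- Matrix::colSums(s != 0)
  act <- as.matrix(Matrix::t(s) %*% x[common, , drop = FALSE])
  act <- sweep(act, 1, pmax(sizes, 1), "/")
  act[sizes == 0, ] <- NA_real_
  dimnames(act) <- list(colnames(s), colnames(x))
  attr(act, "empty") <- colnames(s)[sizes == 0]
  act
}
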