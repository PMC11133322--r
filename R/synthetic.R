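#' Define a synthetic study scenario
#'
#' Fixes every knob of the ground-truthed generator: network size and
#' density, edge-sign balance, weight/activity scales, observation noise,
#' prior corruption (sign flips, spurious and missing edges), knockout
#' design and seed. Generation is a pure function of the scenario, so a
#' scenario plus seed fully reproduces a study.
#'
#' @param g number of genes (includes the \code{h} TF-encoding genes).
#' @param h number of TFs.
#' @param n number of baseline samples (knockout samples are appended).
#' @param density per-TF probability that a gene is targeted.
#' @param pos_fraction fraction of activating (+1) edges.
#' @param weight_scale sd of the half-normal edge magnitudes.
#' @param activity_scale sd of the half-normal activities.
#' @param noise_sd observation noise sd on the expression scale.
#' @param flip_frac,fp_frac,fn_frac prior corruption: fraction of edges with
#'   flipped signs, spurious added edges, and deleted edges.
#' @param ko_tfs TF ids (or indices) receiving one knockout sample each.
#' @param ko_effect multiplicative knockdown in [0, 1]; 1 = full knockout.
#' @param tf_self_weight weight of the structural TF -> own-gene edge that
#'   makes TF expression a noisy readout of its activity (the expression
#'   proxy used by sign prefiltering); excluded from the prior and the
#'   gold-standard signs.
#' @param seed integer seed.
#' @return validated scenario (list with class "SyntheticScenario").
#' @export
syntheticScenario <- function(g = 200, h = 20, n = 60, density = 0.1,
                              pos_fraction = 0.5, weight_scale = 1,
                              activity_scale = 1, noise_sd = 0.2,
                              flip_frac = 0, fp_frac = 0, fn_frac = 0,
                              ko_tfs = character(), ko_effect = 1,
                              tf_self_weight = 1, seed = 1) {
  s <- list(g = as.integer(g), h = as.integer(h), n = as.integer(n),
            density = density, pos_fraction = pos_fraction,
            weight_scale = weight_scale, activity_scale = activity_scale,
            noise_sd = noise_sd, flip_frac = flip_frac, fp_frac = fp_frac,
            fn_frac = fn_frac, ko_tfs = ko_tfs, ko_effect = ko_effect,
            tf_self_weight = tf_self_weight, seed = as.integer(seed))
  stopifnot(s$g > s$h, s$h >= 1, s$n >= 2,
            s$density > 0, s$density <= 1,
            s$pos_fraction >= 0, s$pos_fraction <= 1,
            s$weight_scale > 0, s$activity_scale > 0, s$noise_sd >= 0,
            s$flip_frac >= 0, s$flip_frac <= 1,
            s$fp_frac >= 0, s$fp_frac <= 1,
            s$fn_frac >= 0, s$fn_frac <= 1,
            s$ko_effect >= 0, s$ko_effect <= 1, s$tf_self_weight > 0)
  if (s$density * s$g < 1)
    stop("density * g < 1 would produce empty regulons")
  class(s) <- "SyntheticScenario"
  s
}

#' @rdname syntheticScenario
#' @param x a scenario; \code{path} a YAML file path.
#' @export
writeScenario <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname syntheticScenario
#' @param path YAML file path.
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(syntheticScenario))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown scenario field(s): ",
                        paste(bad, collapse = ", "))
  do.call(syntheticScenario, vals)
}

#' Generate ground truth from a scenario
#'
#' Runs the generative model forward: sparse signed \code{W_true} (per-TF
#' targets drawn independently with probability \code{density}, half-normal
#' magnitudes, signs by \code{pos_fraction}), non-negative half-normal
#' activities \code{Z_true}, and \code{X = W_true Z_true + noise} followed
#' by gene-wise z-scoring. The first \code{h} genes encode the TFs and carry
#' a structural self-edge so their expression tracks the TF's activity.
#' One knockout sample per entry of \code{ko_tfs} is appended, with that
#' TF's activity scaled by \code{1 - ko_effect} and expression regenerated
#' through the same equation.
#'
#' @param scenario a \code{\link{syntheticScenario}}.
#' @return list with elements \code{W_true} (genes x TFs, includes
#'   self-edges), \code{gold} (sparse gold-standard signs, self-edges
#'   excluded), \code{prior_true} (the uncorrupted \linkS4class{PriorNetwork}),
#'   \code{Z_true} (TFs x samples incl. knockouts), \code{X} (z-scored),
#'   \code{X_raw} (before z-scoring), \code{ko_map} (sample -> TF) and
#'   \code{scenario}.
#' @export
generateTruth <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  tf_ids <- sprintf("TF%03d", seq_len(s$h))
  gene_ids <- c(tf_ids, sprintf("G%04d", seq_len(s$g - s$h)))
  W <- matrix(0, s$g, s$h, dimnames = list(gene_ids, tf_ids))
  for (j in seq_len(s$h)) {
    cand <- setdiff(seq_len(s$g), j)
    tgt <- cand[stats::runif(length(cand)) < s$density]
    if (length(tgt) == 0L) tgt <- sample(cand, 1L)
    mag <- abs(stats::rnorm(length(tgt), 0, s$weight_scale))
    sgn <- ifelse(stats::runif(length(tgt)) < s$pos_fraction, 1, -1)
    W[tgt, j] <- mag * sgn
  }
  gold <- Matrix::Matrix(sign(W), sparse = TRUE)
  for (j in seq_len(s$h)) W[j, j] <- s$tf_self_weight

  ko_tfs <- if (is.numeric(s$ko_tfs)) tf_ids[s$ko_tfs] else s$ko_tfs
  if (length(ko_tfs) && !all(ko_tfs %in% tf_ids))
    stop("unknown knockout TF(s): ",
         paste(setdiff(ko_tfs, tf_ids), collapse = ", "))
  Z <- matrix(abs(stats::rnorm(s$h * s$n, 0, s$activity_scale)), s$h, s$n,
              dimnames = list(tf_ids, sprintf("S%03d", seq_len(s$n))))
  if (length(ko_tfs)) {
    Zko <- vapply(seq_along(ko_tfs), function(k) {
      z <- Z[, (k - 1L) %% s$n + 1L]
      z[ko_tfs[k]] <- z[ko_tfs[k]] * (1 - s$ko_effect)
      z
    }, numeric(s$h))
    colnames(Zko) <- paste0("KO_", ko_tfs)
    Z <- cbind(Z, Zko)
  }
  X_raw <- W %*% Z + matrix(stats::rnorm(s$g * ncol(Z), 0, s$noise_sd),
                            s$g, ncol(Z))
  dimnames(X_raw) <- list(gene_ids, colnames(Z))
  X <- suppressWarnings(standardizeExpression(X_raw))
  ko_map <- stats::setNames(ko_tfs, if (length(ko_tfs))
    paste0("KO_", ko_tfs) else character())
  list(W_true = W, gold = as(gold, "CsparseMatrix"),
       prior_true = new("PriorNetwork", signs = drop0(as(as(gold,
         "generalMatrix"), "CsparseMatrix"))),
       Z_true = Z, X = X, X_raw = X_raw, ko_map = ko_map, scenario = s)
}

#' Corrupt a gold-standard network into a study prior
#'
#' Exactly \code{round(flip_frac * E)} uniformly chosen edges get negated
#' signs, \code{round(fn_frac * E)} further (distinct) edges are deleted,
#' and \code{round(fp_frac * E)} spurious edges with random signs are added
#' on uniformly chosen non-edges (TF own-gene cells excluded). Deterministic
#' under \code{seed}.
#'
#' @param gold gold-standard sign matrix (genes x TFs, sparse or dense) or a
#'   \linkS4class{PriorNetwork}.
#' @param flip_frac,fp_frac,fn_frac corruption fractions in [0, 1].
#' @param seed integer seed.
#' @return a corrupted \linkS4class{PriorNetwork}.
#' @export
corruptPrior <- function(gold, flip_frac = 0, fp_frac = 0, fn_frac = 0,
                         seed = 1) {
  stopifnot(flip_frac >= 0, flip_frac <= 1, fp_frac >= 0, fp_frac <= 1,
            fn_frac >= 0, fn_frac <= 1)
  if (is(gold, "PriorNetwork")) gold <- priorSigns(gold)
  m <- as.matrix(gold)
  set.seed(seed)
  edges <- which(m != 0)
  E <- length(edges)
  nflip <- round(flip_frac * E)
  ndel <- round(fn_frac * E)
  if (nflip + ndel > E)
    stop("flip_frac + fn_frac corrupt more edges than exist")
  sel <- sample(E, nflip + ndel)
  if (nflip > 0) m[edges[sel[seq_len(nflip)]]] <-
    -m[edges[sel[seq_len(nflip)]]]
  if (ndel > 0) m[edges[sel[nflip + seq_len(ndel)]]] <- 0
  nfp <- round(fp_frac * E)
  if (nfp > 0) {
    self <- which(outer(rownames(m), colnames(m), "=="))
    avail <- setdiff(which(m == 0), c(edges, self))
    if (nfp > length(avail))
      stop("not enough non-edges to add the requested spurious edges")
    add <- sample(avail, nfp)
    m[add] <- sample(c(-1, 1), nfp, replace = TRUE)
  }
  PriorNetwork(m)
}

#' Simulate one knockout sample
#'
#' Copies an activity column, scales the knocked-out TF's activity by
#' \code{1 - ko_effect}, and regenerates the expression column through the
#' generative equation with the scenario's noise level.
#'
#' @param truth output of \code{\link{generateTruth}}.
#' @param tf the TF to knock out.
#' @param ko_effect knockdown strength in [0, 1]; default the scenario's.
#' @param sample which baseline column to copy (index or id).
#' @return list with the knocked-out activity column \code{z} and the
#'   regenerated expression column \code{x}.
#' @export
simulateKnockout <- function(truth, tf, ko_effect = NULL, sample = 1) {
  if (is.null(ko_effect)) ko_effect <- truth$scenario$ko_effect
  stopifnot(ko_effect >= 0, ko_effect <= 1)
  if (!tf %in% rownames(truth$Z_true)) stop("unknown TF: ", tf)
  z <- truth$Z_true[, sample]
  z[tf] <- z[tf] * (1 - ko_effect)
  x <- as.vector(truth$W_true %*% z) +
    stats::rnorm(nrow(truth$W_true), 0, truth$scenario$noise_sd)
  names(x) <- rownames(truth$W_true)
  list(z = z, x = x)
}

#' Generate synthetic per-edge evidence scores
#'
#' Emulates external evidence (ChIP-like) for the edges of a study prior:
#' edges present in the gold standard draw exponential scores with mean
#' \code{enrichment}, spurious prior edges with mean 1, so true edges are
#' stochastically larger by the enrichment factor.
#'
#' @param gold gold-standard sign matrix or \linkS4class{PriorNetwork}.
#' @param prior the (possibly corrupted) \linkS4class{PriorNetwork} whose
#'   edges receive scores.
#' @param enrichment mean-score ratio of true to spurious edges (> 1).
#' @param seed integer seed.
#' @return data.frame with columns tf, gene, score.
#' @export
generateEdgeScores <- function(gold, prior, enrichment = 3, seed = 1) {
  stopifnot(enrichment > 1)
  if (is(gold, "PriorNetwork")) gold <- priorSigns(gold)
  gold <- as.matrix(gold)
  set.seed(seed)
  df <- priorEdges(prior)
  is_true <- gold[cbind(match(df$gene, rownames(gold)),
                        match(df$tf, colnames(gold)))] != 0
  is_true[is.na(is_true)] <- FALSE
  df$score <- stats::rexp(nrow(df), rate = 1 / ifelse(is_true, enrichment, 1))
  df[order(df$tf, df$gene), c("tf", "gene", "score")]
}
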