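#' @useDynLib tiger, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Model hyperparameters
#'
#' Inverse-gamma shape/scale for the per-edge weight variances
#' (\code{a_alpha}, \code{b_alpha}) and the noise variance (\code{a_sigma},
#' \code{b_sigma}), and the prior variance \code{sigma_z2} of the
#' non-negative TF activities (\eqn{\Sigma_Z = \sigma_Z^2 I}). Defaults are
#' the model's standard weakly-informative settings: all inverse-gamma
#' parameters 1 and \eqn{\sigma_Z^2 = 100}.
#'
#' @param a_alpha,b_alpha,a_sigma,b_sigma,sigma_z2 positive reals.
#' @return named list of validated hyperparameters.
#' @export
tigerHyper <- function(a_alpha = 1, b_alpha = 1, a_sigma = 1, b_sigma = 1,
                       sigma_z2 = 100) {
  h <- list(a_alpha = a_alpha, b_alpha = b_alpha, a_sigma = a_sigma,
            b_sigma = b_sigma, sigma_z2 = sigma_z2)
  if (!all(vapply(h, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  logical(1))))
    stop("all hyperparameters must be strictly positive scalars")
  h
}

#' Fit configuration
#'
#' @param method "VI" (mean-field variational inference; default) or "MCMC"
#'   (Hamiltonian Monte Carlo on the same transformed posterior).
#' @param max_iter maximum VI gradient steps.
#' @param elbo_tol relative ELBO change declaring convergence; checked on
#'   block-averaged ELBO values and required over a 10-check window.
#' @param learning_rate Adam step size.
#' @param mc_samples reparameterized draws per gradient step.
#' @param summary_draws posterior draws used for constrained-scale means/sds.
#' @param mcmc_draws,mcmc_warmup,mcmc_chains MCMC sampling sizes.
#' @param seed integer seed; all randomness in a fit flows from it.
#' @return named list of validated settings.
#' @export
tigerControl <- function(method = c("VI", "MCMC"), max_iter = 50000,
                         elbo_tol = 1e-4, learning_rate = 0.01,
                         mc_samples = 1, summary_draws = 300,
                         mcmc_draws = 1000, mcmc_warmup = 1000,
                         mcmc_chains = 4, seed = 1) {
  method <- match.arg(method)
  cfg <- list(method = method, max_iter = as.integer(max_iter),
              elbo_tol = elbo_tol, learning_rate = learning_rate,
              mc_samples = as.integer(mc_samples),
              summary_draws = as.integer(summary_draws),
              mcmc_draws = as.integer(mcmc_draws),
              mcmc_warmup = as.integer(mcmc_warmup),
              mcmc_chains = as.integer(mcmc_chains), seed = as.integer(seed))
  pos <- c("max_iter", "elbo_tol", "learning_rate", "mc_samples",
           "summary_draws", "mcmc_draws", "mcmc_warmup", "mcmc_chains")
  if (!all(vapply(cfg[pos], function(v) v > 0, logical(1))))
    stop("fit configuration values must be positive")
  cfg
}

# edge arrays (0-based) and C++ family codes from a constraint table
.edge_arrays <- function(constraints) {
  fam <- constraints@family
  idx <- which(fam != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("constraint table contains no edges")
  famc <- fam[idx]
  list(ei = idx[, 1] - 1L, ej = idx[, 2] - 1L,
       fam = ifelse(famc == 3L, 0L, famc),  # 0 free, 1 pos, 2 neg
       names = paste0(colnames(fam)[idx[, 2]], "->", rownames(fam)[idx[, 1]]))
}

#' Log joint density of the generative model
#'
#' \deqn{\log p(X, W, Z, \alpha, \sigma_\epsilon^2) =
#'   \sum_n \log N(X_n \mid W Z_n, \sigma_\epsilon^2 I)
#'   + \sum_{ij} \log p(W_{ij} \mid \alpha_{ij})
#'   + \sum_{ij} \log IG(\alpha_{ij} \mid a_\alpha, b_\alpha)
#'   + \sum_{hn} \log N^+(Z_{hn} \mid 0, \sigma_Z^2)
#'   + \log IG(\sigma_\epsilon^2 \mid a_\sigma, b_\sigma)}
#' where the weight prior is a half-normal (density doubled on the allowed
#' half-line, zero outside) for sign-constrained edges and a full normal for
#' free edges. Returns \code{-Inf} when a constrained edge has the wrong
#' sign or any activity is negative.
#'
#' @param x expression matrix genes x samples.
#' @param W weight matrix genes x TFs, zero where the family is ZERO.
#' @param Z activity matrix TFs x samples, non-negative.
#' @param alpha edge variances: matrix genes x TFs (used where family is not
#'   ZERO) or a single positive scalar.
#' @param sigma_eps2 noise variance, positive scalar.
#' @param constraints a \linkS4class{ConstraintTable}.
#' @param hyper hyperparameters from \code{\link{tigerHyper}}.
#' @return the log joint density (scalar).
#' @export
logJoint <- function(x, W, Z, alpha, sigma_eps2, constraints,
                     hyper = tigerHyper()) {
  if (anyNA(x) || anyNA(W) || anyNA(Z) || anyNA(alpha) || is.na(sigma_eps2))
    stop("NaN/NA input to logJoint")
  fam <- constraints@family
  if (length(alpha) == 1L) alpha <- matrix(alpha, nrow(fam), ncol(fam))
  stopifnot(sigma_eps2 > 0, all(alpha > 0))
  edge <- fam != 0L
  if (any(W[!edge] != 0)) stop("W must be zero where the prior sign is zero")
  if (any(Z < 0) || any(W[fam == 1L] <= 0) || any(W[fam == 2L] >= 0))
    return(-Inf)
  n <- ncol(x); g <- nrow(x)
  resid <- x - W %*% Z
  ll <- -0.5 * g * n * log(2 * pi * sigma_eps2) -
    sum(resid^2) / (2 * sigma_eps2)
  w <- W[edge]; a <- alpha[edge]
  lw <- sum(-0.5 * log(2 * pi * a) - w^2 / (2 * a)) +
    log(2) * sum(fam %in% c(1L, 2L))
  lig <- function(v, sh, sc) sh * log(sc) - lgamma(sh) - (sh + 1) * log(v) -
    sc / v
  la <- sum(lig(a, hyper$a_alpha, hyper$b_alpha))
  lz <- sum(log(2) - 0.5 * log(2 * pi * hyper$sigma_z2) -
              Z^2 / (2 * hyper$sigma_z2))
  ls <- lig(sigma_eps2, hyper$a_sigma, hyper$b_sigma)
  ll + lw + la + lz + ls
}

# deterministic initialization: small signed weights, per-sample NNLS
# activities against an evidence-informed sign matrix (hard-constraint sign
# where assigned, else the sign of the partial correlation, else the prior
# sign), plus seeded jitter. Using the constraint evidence rather than the
# raw prior makes the starting mode robust to sign-corrupted priors.
.init_params <- function(x, constraints, ed, hyper) {
  g <- nrow(x); n <- ncol(x); h <- ncol(constraints@family)
  E <- length(ed$ei)
  fam <- constraints@family
  s <- as.matrix(constraints@priorSigns)
  pc_sign <- sign(constraints@pcor)
  pc_sign[is.na(pc_sign)] <- 0
  free_evid <- fam == 3L & pc_sign != 0
  s[fam == 1L] <- 1
  s[fam == 2L] <- -1
  s[free_evid] <- pc_sign[free_evid]
  u_w <- ifelse(ed$fam == 0L, 0, log(0.1))
  z0 <- matrix(0.1, h, n)
  for (j in seq_len(n)) {
    fit <- try(pracma::lsqnonneg(s, x[, j])$x, silent = TRUE)
    if (!inherits(fit, "try-error")) z0[, j] <- fit
  }
  u_z <- log(pmax(z0, 1e-2))
  m <- c(u_w, rep(0, E), as.vector(u_z), 0)
  m + stats::rnorm(length(m), sd = 0.01)
}

#' Fit the factorization model
#'
#' Estimates the posterior over the signed regulatory network W and the
#' non-negative TF activities Z given a z-scored expression matrix and a
#' constraint table. Sign-constrained weight magnitudes, activities, edge
#' variances and the noise variance are log-transformed to the real line
#' (free-sign edges stay untransformed) and a fully factorized Gaussian
#' variational family is optimized on that space by stochastic gradient
#' ascent on the ELBO with reparameterized draws; posterior means and sds
#' are recovered on the constrained scale by Monte-Carlo averaging. With
#' \code{method = "MCMC"} a Hamiltonian Monte Carlo sampler targets the same
#' transformed posterior (useful as a cross-check on small instances).
#'
#' @param x expression matrix genes x samples (z-scored; see
#'   \code{\link{standardizeExpression}}), aligned with the constraints.
#' @param constraints a \linkS4class{ConstraintTable} from
#'   \code{\link{assignConstraints}}.
#' @param hyper hyperparameters, see \code{\link{tigerHyper}}.
#' @param control fit settings, see \code{\link{tigerControl}}.
#' @return a \linkS4class{TigerFit}.
#' @export
tigerFit <- function(x, constraints, hyper = tigerHyper(),
                     control = tigerControl()) {
  fam <- constraints@family
  if (!identical(rownames(x), rownames(fam)))
    stop("expression matrix and constraints are not aligned; run alignData()")
  if (ncol(fam) < 1L) stop("need at least one TF")
  if (ncol(x) < 2L) stop("need at least two samples")
  if (anyNA(x)) stop("missing values in expression matrix")
  ed <- .edge_arrays(constraints)
  g <- nrow(x); n <- ncol(x); h <- ncol(fam)
  set.seed(control$seed)
  m0 <- .init_params(x, constraints, ed, hyper)
  P <- length(m0)

  if (control$method == "VI") {
    ls0 <- rep(log(0.1), P)
    steps_per_draw <- max(1L, control$mc_samples)  # one draw per step
    res <- cpp_advi(x, ed$ei, ed$ej, ed$fam, h, hyper, m0, ls0,
                    control$max_iter, control$learning_rate,
                    control$elbo_tol, 100L, 10L)
    trace <- as.numeric(res$elbo_trace)
    if (length(trace) >= 2 && utils::tail(trace, 1) < trace[1])
      stop("ELBO diverged (final below initial); try a smaller learning_rate")
    sm <- cpp_vi_summary(ed$ei, ed$ej, ed$fam, g, h, n, res$m, res$ls,
                         max(200L, control$summary_draws))
    converged <- isTRUE(res$converged)
    iterations <- as.integer(res$iterations)
  } else {
    inits <- lapply(seq_len(control$mcmc_chains), function(c)
      m0 + stats::rnorm(P, sd = 0.05))
    sm <- cpp_hmc(x, ed$ei, ed$ej, ed$fam, h, hyper, inits,
                  control$mcmc_warmup, control$mcmc_draws, 20L, 0.8)
    trace <- numeric()
    converged <- TRUE
    iterations <- control$mcmc_warmup + control$mcmc_draws
  }

  dn <- dimnames(fam)
  W_mean <- sm$W_mean; W_sd <- sm$W_sd
  dimnames(W_mean) <- dn; dimnames(W_sd) <- dn
  Z_mean <- sm$Z_mean; Z_sd <- sm$Z_sd
  dimnames(Z_mean) <- list(colnames(fam), colnames(x))
  dimnames(Z_sd) <- dimnames(Z_mean)
  alpha <- as.numeric(sm$alpha_mean)
  names(alpha) <- ed$names
  fit <- new("TigerFit", W_mean = W_mean, W_sd = W_sd, Z_mean = Z_mean,
             Z_sd = Z_sd, alpha_mean = alpha,
             sigma_eps2_mean = as.numeric(sm$sigma_eps2_mean),
             elbo_trace = trace, method = control$method, config = control,
             hyper = hyper, constraint_counts = familyCounts(constraints),
             converged = converged, iterations = iterations)
  validObject(fit)
  fit
}

#' K-fold predictive cross-validation
#'
#' Samples are partitioned into \code{k} folds; the model is refit on each
#' training split and held-out samples are scored by the Gaussian predictive
#' log density under the posterior mean network, with held-out activities
#' estimated by non-negative least squares against \code{W_mean}.
#'
#' @param x expression matrix genes x samples.
#' @param constraints a \linkS4class{ConstraintTable}.
#' @param hyper,control as in \code{\link{tigerFit}}.
#' @param k number of folds, between 2 and the number of samples
#'   (\code{k = n} is leave-one-out).
#' @return mean held-out predictive log density per sample, with per-fold
#'   values in \code{attr(, "folds")}.
#' @export
crossValidate <- function(x, constraints, hyper = tigerHyper(),
                          control = tigerControl(), k = 5) {
  n <- ncol(x)
  if (k > n) stop("k must not exceed the number of samples")
  if (k < 2) stop("k must be at least 2")
  set.seed(control$seed)
  fold <- sample(rep_len(seq_len(k), n))
  scores <- numeric(0)
  fold_means <- numeric(k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    fit <- tigerFit(x[, -test, drop = FALSE], constraints, hyper, control)
    W <- networkWeights(fit)
    s2 <- noiseVariance(fit)
    sc <- vapply(test, function(j) {
      z <- pracma::lsqnonneg(W, x[, j])$x
      sum(stats::dnorm(x[, j], W %*% z, sqrt(s2), log = TRUE))
    }, numeric(1))
    scores <- c(scores, sc)
    fold_means[f] <- mean(sc)
  }
  out <- mean(scores)
  attr(out, "folds") <- fold_means
  out
}
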