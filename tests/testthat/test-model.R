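test_that("log joint matches the closed-form densities on a 1x1x1 model", {
  x <- matrix(0, 1, 1, dimnames = list("g1", "s1"))
  s <- matrix(1, 1, 1, dimnames = list("g1", "tf1"))
  pc <- matrix(0, 1, 1, dimnames = dimnames(s))   # zero pcor -> FREE_NORMAL
  ct <- assignConstraints(PriorNetwork(s), pcor = pc)
  expect_equal(constraintFamilies(ct)[1, 1], "FREE_NORMAL")
  W <- matrix(0, 1, 1); Z <- matrix(0, 1, 1)
  got <- logJoint(x, W, Z, alpha = 1, sigma_eps2 = 1, ct)
  # independent oracle: sum of five univariate log densities
  expected <- dnorm(0, 0, 1, log = TRUE) +                 # likelihood
    dnorm(0, 0, 1, log = TRUE) +                           # free W prior
    lig_oracle(1, 1, 1) +                                  # alpha
    (log(2) + dnorm(0, 0, 10, log = TRUE)) +               # half-normal Z
    lig_oracle(1, 1, 1)                                    # sigma_eps2
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("log joint is -Inf outside the constrained support", {
  x <- matrix(c(0.5, -0.5), 1, 2, dimnames = list("g1", c("s1", "s2")))
  s <- matrix(1, 1, 1, dimnames = list("g1", "tf1"))
  pc <- matrix(0.5, 1, 1, dimnames = dimnames(s))
  ct <- assignConstraints(PriorNetwork(s), pcor = pc)
  expect_equal(constraintFamilies(ct)[1, 1], "POS_HALF_NORMAL")
  Z <- matrix(c(0.1, 0.2), 1, 2)
  expect_equal(logJoint(x, matrix(-0.5, 1, 1), Z, 1, 1, ct), -Inf)
  expect_true(is.finite(logJoint(x, matrix(0.5, 1, 1), Z, 1, 1, ct)))
  expect_equal(logJoint(x, matrix(0.5, 1, 1), -Z, 1, 1, ct), -Inf)
})

test_that("duplicating samples doubles the likelihood and activity terms only", {
  inst <- tiny_instance(seed = 2, g = 10, h = 2, n = 5, density = 0.4)
  x <- inst$x
  fam <- constraintFamilies(inst$ct)
  W <- matrix(0, nrow(x), 2, dimnames = dimnames(fam))
  W[fam == "POS_HALF_NORMAL"] <- 0.2
  W[fam == "NEG_HALF_NORMAL"] <- -0.2
  W[fam == "FREE_NORMAL"] <- 0.1
  Z <- matrix(0.5, 2, ncol(x))
  l1 <- logJoint(x, W, Z, 1, 1, inst$ct)
  l2 <- logJoint(cbind(x, x), W, cbind(Z, Z), 1, 1, inst$ct)
  # difference equals one more copy of likelihood + Z prior; W/alpha/sigma fixed
  g <- nrow(x); n <- ncol(x)
  ll <- -0.5 * g * n * log(2 * pi) - sum((x - W %*% Z)^2) / 2
  lz <- sum(log(2) - 0.5 * log(2 * pi * 100) - Z^2 / 200)
  expect_equal(l2 - l1, ll + lz, tolerance = 1e-8)
})

test_that("half-normal edges keep their sign and ZERO edges stay zero", {
  sh <- shared_fit()
  W <- networkWeights(sh$fit)
  fam <- constraintFamilies(sh$inst$ct)
  expect_true(all(W[fam == "ZERO"] == 0))
  expect_true(all(W[fam == "POS_HALF_NORMAL"] > 0))
  expect_true(all(W[fam == "NEG_HALF_NORMAL"] < 0))
  expect_true(all(activities(sh$fit) >= 0))
})

test_that("identical seeds reproduce the fit exactly", {
  inst <- tiny_instance(seed = 4, g = 15, h = 3, n = 10, density = 0.3)
  ctl <- tigerControl(seed = 11, max_iter = 2000)
  f1 <- tigerFit(inst$x, inst$ct, control = ctl)
  f2 <- tigerFit(inst$x, inst$ct, control = ctl)
  expect_identical(networkWeights(f1), networkWeights(f2))
  expect_identical(activities(f1), activities(f2))
  expect_identical(elboTrace(f1), elboTrace(f2))
})

test_that("zero data pulls free weights to zero", {
  g <- 10; n <- 12
  x <- matrix(0, g, n, dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  x[] <- rnorm(g * n, sd = 1e-6)  # break exact constancy for alignment
  s <- matrix(1, g, 2, dimnames = list(rownames(x), c("tf1", "tf2")))
  pc <- matrix(0, g, 2, dimnames = dimnames(s))  # all FREE
  ct <- assignConstraints(PriorNetwork(s), pcor = pc)
  fit <- tigerFit(x, ct, control = tigerControl(seed = 1, max_iter = 10000))
  expect_lt(max(abs(networkWeights(fit))), 0.1)
})

test_that("smoothed ELBO is non-decreasing near convergence", {
  sh <- shared_fit()
  tr <- elboTrace(sh$fit)
  last <- tail(tr, 10)
  tol <- 1e-3 * abs(tail(tr, 1))
  expect_true(all(diff(last) > -tol))
})

test_that("reconstruction is invariant under joint regulon renormalization", {
  sh <- shared_fit()
  W <- networkWeights(sh$fit)
  Z <- activities(sh$fit)
  d <- colSums(abs(W))
  Wn <- normalizeRegulons(W)
  Zn <- Z * d
  rel <- norm(W %*% Z - Wn %*% Zn, "F") / norm(W %*% Z, "F")
  expect_lt(rel, 0.02)
})

test_that("spurious prior edges are shrunk relative to true edges", {
  sc <- syntheticScenario(g = 80, h = 8, n = 40, density = 0.2,
                          noise_sd = 0.2, fp_frac = 1, seed = 6)
  tr <- generateTruth(sc)
  prior <- corruptPrior(tr$gold, fp_frac = 1, seed = 6)  # half the edges spurious
  al <- alignData(tr$X, prior)
  ct <- assignConstraints(al$prior, al$expression)
  fit <- tigerFit(al$expression, ct,
                  control = tigerControl(seed = 6, max_iter = 20000))
  W <- networkWeights(fit)
  gold <- as.matrix(tr$gold)
  pe <- priorEdges(al$prior)
  is_true <- gold[cbind(match(pe$gene, rownames(gold)),
                        match(pe$tf, colnames(gold)))] != 0
  w <- abs(W[cbind(match(pe$gene, rownames(W)), match(pe$tf, colnames(W)))])
  expect_lt(mean(w[!is_true]), 0.5 * mean(w[is_true]))
})

test_that("cross-validation prefers structured data over permuted labels", {
  scores <- sapply(1:3, function(sd) {
    inst <- tiny_instance(seed = sd, g = 20, h = 3, n = 12, density = 0.4,
                          noise_sd = 0.05)
    ctl <- tigerControl(seed = sd, max_iter = 8000)
    cv <- crossValidate(inst$x, inst$ct, control = ctl, k = 3)
    set.seed(sd)
    xp <- inst$x[sample(nrow(inst$x)), ]
    rownames(xp) <- rownames(inst$x)
    cvp <- crossValidate(xp, inst$ct, control = ctl, k = 3)
    c(cv, cvp)
  })
  expect_true(all(scores[1, ] > scores[2, ]))
})

test_that("cross-validation folds are valid and deterministic", {
  inst <- tiny_instance(seed = 8, g = 12, h = 2, n = 6, density = 0.4)
  ctl <- tigerControl(seed = 2, max_iter = 3000)
  expect_error(crossValidate(inst$x, inst$ct, control = ctl, k = 7),
               "exceed")
  cv1 <- crossValidate(inst$x, inst$ct, control = ctl, k = 6)  # leave-one-out
  expect_length(attr(cv1, "folds"), 6L)
  cv2 <- crossValidate(inst$x, inst$ct, control = ctl, k = 6)
  expect_identical(as.numeric(cv1), as.numeric(cv2))
})
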