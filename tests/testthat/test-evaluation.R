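test_that("rank percentiles use ascending average ranks", {
  expect_equal(rankPercentile(c(10, 20, 30)), c(1, 2, 3) / 3)
  k <- 5
  expect_equal(rankPercentile(rep(2, k)), rep((k + 1) / (2 * k), k))
  expect_equal(rankPercentile(7), 1)
  expect_error(rankPercentile(numeric()), "empty")
  expect_error(rankPercentile(c(1, Inf)), "finite")
})

test_that("regulon quality score is the L1-weighted evidence mean", {
  # uniform weights reduce to the arithmetic mean of the evidence
  expect_equal(regulonQS(rep(1, 4), c(0.2, 0.4, 0.6, 0.8)), 0.5)
  expect_equal(regulonQS(c(1, 0), c(0.2, 0.9)), 0.2)
  # signs are ignored: (+1, -1) normalizes to (0.5, 0.5)
  expect_equal(regulonQS(c(1, -1), c(0.4, 0.8)), 0.6)
  # invariant under positive rescaling
  set.seed(2)
  w <- rnorm(6); s <- runif(6)
  expect_equal(regulonQS(w, s), regulonQS(3.7 * w, s))
  expect_error(regulonQS(c(1, 1), c(0.5)), "length")
  expect_error(regulonQS(c(0, 0), c(0.5, 0.5)), "zero")
})

test_that("the QS report computes prior mean, posterior QS and improvement", {
  W <- cbind(tfA = c(3, 1, 0), tfB = c(0, 1, 1))
  rownames(W) <- c("g1", "g2", "g3")
  sc <- data.frame(tf = c("tfA", "tfA", "tfB", "tfB"),
                   gene = c("g1", "g2", "g2", "g3"),
                   score = c(10, 2, 4, 8))
  rep <- regulonQSReport(W, sc)
  expect_equal(rep$prior_qs, c(0.75, 0.75))
  expect_equal(rep$posterior_qs[rep$tf == "tfA"], 0.75 * 1 + 0.25 * 0.5)
  expect_equal(rep$improvement,
               (rep$posterior_qs - rep$prior_qs) / rep$prior_qs)
})

test_that("RBO identities hold and match the brute-force depth summation", {
  expect_equal(rbo(letters[1:5], letters[1:5], 0.9), 1)
  expect_equal(rbo(letters[1:4], letters[10:13], 0.9), 0)
  for (p in c(0.5, 0.9, 0.98)) {
    expect_equal(rbo(c("x", "y", "z"), c("y", "x", "z"), p),
                 rbo_bruteforce(c("x", "y", "z"), c("y", "x", "z"), p),
                 tolerance = 1e-12)
    a <- letters[1:5]; b <- c("b", "a", "d", "c", "e")
    expect_equal(rbo(a, b, p), rbo_bruteforce(a, b, p), tolerance = 1e-12)
  }
})

test_that("RBO is symmetric and decreases with top swaps", {
  a <- letters[1:8]
  b <- c("c", "a", "h", "b", "e", "d", "g", "f")
  expect_equal(rbo(a, b, 0.98), rbo(b, a, 0.98))
  swapped <- a
  vals <- numeric(4)
  for (k in 1:4) {
    swapped[c(2 * k - 1, 2 * k)] <- swapped[c(2 * k, 2 * k - 1)]
    vals[k] <- rbo(a, swapped, 0.9)
  }
  expect_true(all(diff(c(1, vals)) < 0))
  expect_error(rbo(c("a", "a"), c("a", "b")), "duplicate")
  expect_error(rbo(a, b, p = 1.2), "p must")
})

test_that("edge-sign accuracy counts matches over the scope", {
  gold <- cbind(tf1 = c(1, -1, 1, -1))
  rownames(gold) <- paste0("g", 1:4)
  W <- cbind(tf1 = c(0.5, -0.5, 0.5, -0.5))
  rownames(W) <- rownames(gold)
  expect_equal(edgeSignAccuracy(W, gold), 1)
  expect_equal(edgeSignAccuracy(-W, gold), 0)
  W2 <- W; W2["g4", 1] <- 0.2
  expect_equal(edgeSignAccuracy(W2, gold), 0.75)
  W3 <- W; W3["g1", 1] <- 0  # no call counts as incorrect
  expect_equal(edgeSignAccuracy(W3, gold), 0.75)
  expect_error(edgeSignAccuracy(W, gold, edges = data.frame(tf = character(),
                                                            gene = character())),
               "empty")
})

test_that("knockout metrics report ranks and top-10 successes", {
  set.seed(3)
  z <- matrix(runif(50 * 3), 50, 3,
              dimnames = list(sprintf("tf%02d", 1:50), c("k1", "k2", "k3")))
  z["tf01", "k1"] <- -1             # lowest in sample k1
  rk <- rankTFA(z, "LOWEST_FIRST")
  km <- knockoutMetrics(rk, c(k1 = "tf01"))
  expect_equal(km$rank, 1)
  expect_true(km$success)
  ord <- order(z[, "k2"])
  km11 <- knockoutMetrics(rk, c(k2 = rownames(z)[ord[11]]))
  expect_false(km11$success)
  # exact tie at ranks 10/11 averages to 10.5, below the cutoff
  z2 <- matrix(c(1:9, 10, 10, 12:50), 50, 1,
               dimnames = list(sprintf("tf%02d", 1:50), "k1"))
  rk2 <- rankTFA(z2, "LOWEST_FIRST")
  km2 <- knockoutMetrics(rk2, c(k1 = "tf10"))
  expect_equal(km2$rank, 10.5)
  expect_false(km2$success)
  expect_error(knockoutMetrics(rk, c(k1 = "nope")), "unknown TF")
  expect_error(knockoutMetrics(rankTFA(z, "HIGHEST_FIRST"), c(k1 = "tf01")),
               "LOWEST_FIRST")
})

test_that("the signed-mean baseline averages sign-weighted expression", {
  x <- rbind(g1 = c(1, 0.5), g2 = c(-1, 0.25))
  colnames(x) <- c("s1", "s2")
  m <- matrix(c(1, -1), 2, 1, dimnames = list(c("g1", "g2"), "tfA"))
  act <- baselineSignedMean(x, PriorNetwork(m))
  expect_equal(unname(act["tfA", ]), c(1, 0.125))
  actf <- baselineSignedMean(x, PriorNetwork(-m))
  expect_equal(unname(actf["tfA", ]), -c(1, 0.125))
  m1 <- matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "tfA"))
  act1 <- baselineSignedMean(x, PriorNetwork(m1))
  expect_equal(unname(act1["tfA", ]), unname(x["g1", ]))
})

test_that("posterior regulons up-weight edges with stronger external evidence", {
  sc <- syntheticScenario(g = 80, h = 8, n = 40, density = 0.2,
                          noise_sd = 0.2, fp_frac = 1, seed = 6)
  tr <- generateTruth(sc)
  prior <- corruptPrior(tr$gold, fp_frac = 1, seed = 6)
  al <- alignData(tr$X, prior)
  ct <- assignConstraints(al$prior, al$expression)
  fit <- tigerFit(al$expression, ct, control = tigerControl(seed = 6))
  scores <- generateEdgeScores(tr$gold, al$prior, enrichment = 3, seed = 6)
  qs <- regulonQSReport(networkWeights(fit), scores)
  expect_gte(mean(qs$posterior_qs > qs$prior_qs), 0.8)
})
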