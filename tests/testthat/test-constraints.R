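test_that("partial correlation recovers the Gaussian closed form", {
  # known 3-variable precision matrix; pcor(i,j) = -Omega_ij/sqrt(Omega_ii Omega_jj)
  omega <- matrix(c(2, -0.8, 0.3,
                    -0.8, 1.5, -0.5,
                    0.3, -0.5, 1.2), 3, 3, byrow = TRUE)
  expect_true(all(eigen(omega)$values > 0))
  sigma <- solve(omega)
  set.seed(11)
  n <- 5000
  x <- t(chol(sigma)) %*% matrix(rnorm(3 * n), 3, n)
  rownames(x) <- c("g1", "g2", "g3")
  pairs <- data.frame(tf = c("g1", "g1", "g2"), gene = c("g2", "g3", "g3"))
  est <- shrinkagePartialCorrelation(x, pairs)
  expected <- c(-omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2]),
                -omega[1, 3] / sqrt(omega[1, 1] * omega[3, 3]),
                -omega[2, 3] / sqrt(omega[2, 2] * omega[3, 3]))
  expect_lt(max(abs(est - expected)), 0.05)
})

test_that("independent genes have near-zero partial correlation", {
  set.seed(5)
  x <- matrix(rnorm(2 * 2000), 2, 2000, dimnames = list(c("a", "b"), NULL))
  colnames(x) <- paste0("s", 1:2000)
  pc <- shrinkagePartialCorrelation(x, data.frame(tf = "a", gene = "b"))
  expect_lt(abs(pc), 0.1)
})

test_that("with two genes the partial correlation is the shrunk correlation", {
  set.seed(9)
  x <- matrix(rnorm(2 * 50), 2, 50, dimnames = list(c("a", "b"), NULL))
  x[2, ] <- 0.7 * x[1, ] + 0.3 * x[2, ]
  rs <- shrinkageCorrelation(x)
  pc <- shrinkagePartialCorrelation(x, data.frame(tf = "a", gene = "b"))
  expect_equal(as.numeric(pc), rs[1, 2], tolerance = 1e-10)
})

test_that("partial correlation validates its inputs", {
  x <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error(shrinkagePartialCorrelation(x, data.frame(tf = "a", gene = "zz")),
               "unknown gene")
  x2 <- x[, 1:2]
  expect_error(shrinkagePartialCorrelation(x2, data.frame(tf = "a", gene = "b")),
               "3 samples")
})

test_that("constraint families follow the sign-agreement truth table", {
  genes <- paste0("g", 1:8)
  s <- matrix(0, 8, 2, dimnames = list(genes, c("tfA", "tfB")))
  # tfA: prior +1 against pcor {+, -, 0, NA}; tfB: prior -1 against the same
  s[1:4, 1] <- 1
  s[5:8, 2] <- -1
  pc <- matrix(NA_real_, 8, 2, dimnames = dimnames(s))
  pc[1:4, 1] <- c(0.3, -0.2, 0, NA)
  pc[5:8, 2] <- c(0.3, -0.2, 0, NA)
  ct <- assignConstraints(PriorNetwork(s), pcor = pc, threshold = 0)
  fam <- constraintFamilies(ct)
  expect_equal(unname(fam[1:4, "tfA"]),
               c("POS_HALF_NORMAL", "FREE_NORMAL", "FREE_NORMAL", "FREE_NORMAL"))
  expect_equal(unname(fam[5:8, "tfB"]),
               c("FREE_NORMAL", "NEG_HALF_NORMAL", "FREE_NORMAL", "FREE_NORMAL"))
  expect_true(all(fam[s == 0] == "ZERO"))
})

test_that("raising the threshold never creates new half-normal constraints", {
  set.seed(21)
  inst <- tiny_instance(seed = 21, g = 30, h = 4, n = 20, density = 0.3)
  for (th in c(0, 0.05, 0.1, 0.3)) {
    ct0 <- assignConstraints(inst$prior, inst$x, threshold = th)
    ct1 <- assignConstraints(inst$prior, inst$x, threshold = th + 0.1)
    hard0 <- ct0@family %in% c(1L, 2L)
    hard1 <- ct1@family %in% c(1L, 2L)
    expect_true(all(hard0 | !hard1))  # hard at th+0.1 => hard at th
  }
})

test_that("flipping all prior signs complements the hard-constraint set", {
  inst <- tiny_instance(seed = 13, g = 30, h = 4, n = 20, density = 0.3)
  ct <- assignConstraints(inst$prior, inst$x)
  flipped <- PriorNetwork(-priorSigns(inst$prior))
  ctf <- assignConstraints(flipped, inst$x)
  # ZERO pattern is untouched
  expect_equal(ctf@family == 0L, ct@family == 0L)
  hard0 <- ct@family %in% c(1L, 2L)
  hard1 <- ctf@family %in% c(1L, 2L)
  # sign agreement becomes disagreement and vice versa, so an edge is hard
  # under exactly one orientation whenever it has nonzero pcor evidence
  expect_false(any(hard0 & hard1))
  evid <- ct@family != 0L & !is.na(ct@pcor) & ct@pcor != 0
  expect_equal(as.vector(hard0 | hard1), as.vector(evid))
  # and the flipped hard families sit opposite the evidence sign
  expect_true(all(ct@pcor[ctf@family == 1L] > 0))
  expect_true(all(ct@pcor[ctf@family == 2L] < 0))
})

test_that("an accurate prior earns more sign constraints than a scrambled one", {
  sc <- syntheticScenario(g = 80, h = 8, n = 50, density = 0.2,
                          noise_sd = 0.1, seed = 17)
  tr <- generateTruth(sc)
  al <- alignData(tr$X, tr$prior_true)
  ct_good <- assignConstraints(al$prior, al$expression)
  set.seed(99)
  s <- priorSigns(al$prior)
  s@x <- sample(c(-1, 1), length(s@x), replace = TRUE)
  ct_rand <- assignConstraints(PriorNetwork(s), al$expression)
  frac <- function(ct) {
    cnt <- familyCounts(ct)
    (cnt[["POS_HALF_NORMAL"]] + cnt[["NEG_HALF_NORMAL"]]) /
      (sum(cnt) - cnt[["ZERO"]])
  }
  expect_gt(frac(ct_good), frac(ct_rand))
})
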