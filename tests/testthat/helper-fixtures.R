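# Shared fixtures, all generated in code.

# tiny aligned instance for fit-level tests
tiny_instance <- function(seed = 1, g = 12, h = 3, n = 8, density = 0.3,
                          noise_sd = 0.1, ...) {
  sc <- syntheticScenario(g = g, h = h, n = n, density = density,
                          noise_sd = noise_sd, seed = seed, ...)
  tr <- generateTruth(sc)
  al <- alignData(tr$X, tr$prior_true)
  ct <- assignConstraints(al$prior, al$expression)
  list(truth = tr, x = al$expression, prior = al$prior, ct = ct)
}

# one moderately sized fit cached across test files
.fit_cache <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    inst <- tiny_instance(seed = 3, g = 40, h = 5, n = 25, density = 0.25)
    .fit_cache$inst <- inst
    .fit_cache$fit <- tigerFit(inst$x, inst$ct,
                               control = tigerControl(seed = 3,
                                                      max_iter = 20000))
  }
  list(fit = .fit_cache$fit, inst = .fit_cache$inst)
}

# simple 3-gene expression fixture on disk
write_tiny_expression <- function(path, vals = rbind(c(1, 3), c(2, 0), c(5, 5)),
                                  genes = c("gene1", "gene2", "gene3"),
                                  samples = c("s1", "s2")) {
  df <- data.frame(gene = genes, vals)
  colnames(df) <- c("gene", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# log inverse-gamma density via dgamma, used as an independent oracle
lig_oracle <- function(x, shape, scale) {
  stats::dgamma(1 / x, shape = shape, rate = scale, log = TRUE) - 2 * log(x)
}

# brute-force extrapolated RBO by direct depth summation (equal-length lists)
rbo_bruteforce <- function(a, b, p) {
  k <- length(a)
  stopifnot(length(b) == k)
  A <- vapply(seq_len(k), function(d)
    length(intersect(a[seq_len(d)], b[seq_len(d)])) / d, numeric(1))
  (1 - p) / p * sum(A * p^seq_len(k)) + A[k] * p^k
}
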