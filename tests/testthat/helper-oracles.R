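# Independent reference implementations used as oracles.

# dense whitened minimum-norm kernel with dSPM normalization, written out
# explicitly via the eigendecomposition of C (independent of the package's
# solve()-based path)
dense_inverse_oracle <- function(g, cv, lambda2) {
  es <- eigen(cv, symmetric = TRUE)
  whitener <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  gw <- whitener %*% g
  alpha <- nrow(g) / sum(diag(gw %*% t(gw)))
  aw <- alpha * gw %*% t(gw) + lambda2 * diag(nrow(g))
  kernel <- alpha * t(gw) %*% solve(aw) %*% whitener
  norm <- sqrt(diag(kernel %*% cv %*% t(kernel)))
  list(kernel = kernel, norm = norm)
}

random_spd <- function(n) {
  a <- matrix(rnorm(n * 2 * n), n)
  tcrossprod(a) / (2 * n)
}

random_expr <- function(seed, n_genes = 10, n_regions = 34) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_regions), n_genes, n_regions,
         dimnames = list(sprintf("G%02d", seq_len(n_genes)), NULL))
}
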