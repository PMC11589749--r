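# Spherical-spline scalp interpolation (Perrin et al. 1989): potentials on
# the unit sphere are modelled as a spline in g(cos(angle)), a series over
# Legendre polynomials. Used to rebuild flagged channels from the remaining
# ones.

# Legendre polynomials P_1..P_n evaluated at x (vector), by recursion
legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  out[, 1] <- x
  if (n >= 2) out[, 2] <- 0.5 * (3 * x^2 - 1)
  if (n >= 3) {
    for (k in 3:n) {
      out[, k] <- ((2 * k - 1) * x * out[, k - 1] -
                     (k - 1) * out[, k - 2]) / k
    }
  }
  out
}

# g(x) kernel of the spherical spline of order m
spline_g <- function(x, m = 4, nterms = 50) {
  n <- seq_len(nterms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  p <- legendre_table(x, nterms)
  as.vector(p %*% coef) / (4 * pi)
}

# transfer matrix mapping potentials at `good` unit-sphere positions to
# spline estimates at `bad` positions
spline_transfer <- function(good, bad, m = 4, nterms = 50, lambda = 1e-5) {
  ng <- nrow(good)
  cosang <- function(a, b) {
    x <- tcrossprod(a, b)
    pmin(1, pmax(-1, x))
  }
  g_gg <- matrix(spline_g(as.vector(cosang(good, good)), m, nterms), ng, ng)
  g_bg <- matrix(spline_g(as.vector(cosang(bad, good)), m, nterms),
                 nrow(bad), ng)
  # spline system with the constant term and ridge regularization
  a <- rbind(cbind(g_gg + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  ainv <- solve(a)
  cbind(g_bg, rep(1, nrow(bad))) %*% ainv[, seq_len(ng), drop = FALSE]
}
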