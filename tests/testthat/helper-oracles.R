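# Independent oracles and small fixture builders used across test files.

# Analytic transient conduction in an infinite cylinder with a convective
# boundary (Robin condition): theta(r, t)/theta0 as a Bessel series.
# Eigenvalues beta_n solve beta J1(beta) = Bi J0(beta).
cylinder_series_T <- function(r, t, radius, alpha, Bi, T0, T_inf,
                              n_terms = 60) {
  f <- function(b) b * besselJ(b, 1) - Bi * besselJ(b, 0)
  grid <- seq(1e-6, (n_terms + 2) * pi, by = 0.01)
  sg <- sign(f(grid))
  idx <- which(diff(sg) != 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1))
  roots <- roots[seq_len(n_terms)]
  Cn <- (2 / roots) * besselJ(roots, 1) /
    (besselJ(roots, 0)^2 + besselJ(roots, 1)^2)
  theta <- sum(Cn * exp(-roots^2 * alpha * t / radius^2) *
                 besselJ(roots * r / radius, 0))
  T_inf + (T0 - T_inf) * theta
}

# A small parameter set for cheap solver tests (same control physics,
# reduced radius so transients complete quickly).
small_params <- function(r = 0.02, ...) {
  p <- unclass(bake_params("control"))
  p$r <- r
  extra <- list(...)
  p[names(extra)] <- extra
  do.call(parameter_set, p)
}
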