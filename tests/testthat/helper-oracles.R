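# Independent oracles used across the suite.

# brute-force all-pairs ion/library matching (quadratic reference)
brute_force_matches <- function(ion_mzs, library, tolerance = 0.003) {
  lapply(ion_mzs, function(mz) {
    err <- mz - library$expected_mz
    keep <- abs(err) <= tolerance
    data.frame(metabolite_id = library$metabolite_id[keep],
               mass_error = err[keep], stringsAsFactors = FALSE)
  })
}

# normal-equations OLS (reference for the QR-based fitter)
normal_equations_fit <- function(X, y) {
  XtX <- t(X) %*% X
  solve(XtX, t(X) %*% y)[, 1]
}

# exhaustive hypergeometric upper tail P(X >= k): enumerate all C(N, n) draws
enumerated_hyper_p <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  inset <- colSums(draws <= K)   # items 1..K are "in the pathway"
  mean(inset >= k)
}

# fixed-step classical RK4 for a 2-state system
rk4_integrate <- function(deriv, y0, t_end, dt) {
  nsteps <- ceiling(t_end / dt)
  y <- y0
  t <- 0
  for (i in seq_len(nsteps)) {
    h <- min(dt, t_end - t)
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (t >= t_end) break
  }
  y
}

coa_deriv <- function(params) {
  vc <- rate_v_coa(params)
  function(t, y) {
    vb <- rate_v_biomass(params, max(y[1], 0))
    c(vc - params$coupling * vb, vb * y[2])
  }
}

# random valid sum formula as a named count vector
random_formula <- function() {
  els <- sample(names(element_masses), sample(1:5, 1))
  stats::setNames(as.integer(sample(1:30, length(els), replace = TRUE)), els)
}
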