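# Minimal Michaelis-Menten model of CoA homeostasis: biosynthesis activated
# by DCA and attenuated by hopantenate, and CoA-consuming biomass production
# that is allosterically inhibited by high CoA (cubic term). Explains
# dichloroacetate toxicity as runaway CoA accumulation.

#' Parameters of the minimal CoA kinetic model
#'
#' Defaults are the published simulation parameter set:
#' \code{v_biomass_max = 1}, \code{K_coa = 0.01}, \code{K_i = 1},
#' \code{v_coa_max = 0.45}, \code{coa_0 = 10}; the treated scenarios use
#' \code{dca = 0.01} and \code{hopan = 5}. \code{K_dca} is not part of the
#' published set (only its role in the biosynthesis rate law is); the default
#' 0.01 equals the default DCA concentration, giving a 1.5-fold activation.
#' All quantities are in the model's arbitrary concentration / flux / time
#' units. \code{K_i} carries concentration-cubed units, as implied by the
#' \code{coa^3 / K_i} inhibition term.
#'
#' @param v_coa_max Maximal CoA biosynthesis flux.
#' @param v_biomass_max Maximal biomass production flux.
#' @param K_coa Michaelis constant of CoA utilization.
#' @param K_i Inhibitory constant of CoA on biomass production
#'   (concentration^3).
#' @param K_dca Michaelis constant of DCA activation of biosynthesis.
#' @param dca DCA concentration (0 = untreated).
#' @param hopan Hopantenate concentration (0 = untreated). Values > 1 divide
#'   the maximal biosynthesis flux; values in (0, 1] leave it unchanged, since
#'   division by a sub-unit concentration would spuriously activate the
#'   inhibited reaction.
#' @param coa_0 Initial CoA concentration.
#' @param biomass_0 Initial biomass (relative units).
#' @param t_end Simulation horizon; the default lets the untreated system
#'   settle within 1e-4 of its fixed point and the DCA runaway exceed ten
#'   times the initial CoA level.
#' @param coupling Stoichiometric consumption of CoA per unit biomass flux.
#' @return List of class \code{coa_model_params}.
#' @export
coa_model_params <- function(v_coa_max = 0.45, v_biomass_max = 1,
                             K_coa = 0.01, K_i = 1, K_dca = 0.01,
                             dca = 0, hopan = 0, coa_0 = 10, biomass_0 = 1,
                             t_end = 250, coupling = 1) {
  p <- list(v_coa_max = v_coa_max, v_biomass_max = v_biomass_max,
            K_coa = K_coa, K_i = K_i, K_dca = K_dca, dca = dca,
            hopan = hopan, coa_0 = coa_0, biomass_0 = biomass_0,
            t_end = t_end, coupling = coupling)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                           is.na(v) || v < 0, logical(1))]
  if (length(bad)) stop(sprintf("parameter '%s' must be a non-negative number", bad[1]))
  if (K_coa <= 0 || K_i <= 0 || K_dca <= 0) stop("K_coa, K_i, K_dca must be positive")
  class(p) <- "coa_model_params"
  p
}

#' CoA biosynthesis rate
#'
#' \code{v = (v_coa_max / max(hopan, 1)) * (dca / (dca + K_dca) + 1)}: DCA
#' activates biosynthesis saturably (factor in (1, 2)); hopantenate
#' concentrations above 1 divide the maximal flux.
#'
#' @param params \code{coa_model_params}.
#' @param coa CoA concentration (unused; the rate law is zero-order in CoA,
#'   kept in the signature for uniformity).
#' @return Flux.
#' @export
rate_v_coa <- function(params, coa = NULL) {
  vmax <- params$v_coa_max / max(params$hopan, 1)
  vmax * (params$dca / (params$dca + params$K_dca) + 1)
}

#' Biomass production rate
#'
#' \code{v = v_biomass_max * coa / (coa + K_coa * (1 + coa^3 / K_i))}:
#' Michaelis-Menten utilization of CoA with ultrasensitive substrate
#' inhibition at high CoA (cubic term), so the rate rises to an interior
#' maximum at \code{coa = (K_i / 2)^(1/3)} and falls toward zero as CoA
#' accumulates.
#'
#' @param params \code{coa_model_params}.
#' @param coa CoA concentration(s), >= 0.
#' @return Flux (vectorized over \code{coa}).
#' @export
rate_v_biomass <- function(params, coa) {
  stopifnot(all(coa >= 0))
  params$v_biomass_max * coa /
    (coa + params$K_coa * (1 + coa^3 / params$K_i))
}

# Dormand-Prince 5(4) adaptive step integrator (two-state systems are tiny;
# a dependency-free implementation keeps the model self-contained).
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

ode_dopri <- function(deriv, y0, times, rtol = 1e-8, atol = 1e-10,
                      max_steps = 5e6) {
  ny <- length(y0)
  out <- matrix(NA_real_, length(times), ny)
  out[1, ] <- y0
  t <- times[1]
  y <- y0
  h <- min(1e-4, diff(range(times)) / 100)
  k <- matrix(0, 7, ny)
  k[1, ] <- deriv(t, y)
  steps <- 0L
  for (iout in 2:length(times)) {
    tout <- times[iout]
    while (t < tout) {
      if ((steps <- steps + 1L) > max_steps) {
        stop(sprintf("ODE integrator exceeded %d steps at t = %.6g (h = %.3g)",
                     max_steps, t, h))
      }
      h <- min(h, tout - t)
      for (s in 2:7) {
        a <- .dp_a[[s - 1]]
        k[s, ] <- deriv(t + .dp_c[s] * h,
                        y + h * colSums(k[seq_along(a), , drop = FALSE] * a))
      }
      y5 <- y + h * colSums(k * .dp_b5)
      y4 <- y + h * colSums(k * .dp_b4)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        t <- t + h
        y <- y5
        k[1, ] <- k[7, ]          # FSAL
        fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
        h <- h * fac
      } else {
        h <- h * max(0.2, 0.9 * err^(-0.2))  # k[1, ] still valid at (t, y)
      }
    }
    out[iout, ] <- y
  }
  out
}

#' Simulate the CoA homeostasis model
#'
#' Integrates \code{dCoA/dt = v_coa - coupling * v_biomass} and
#' \code{dB/dt = v_biomass * B} with an adaptive Dormand-Prince 5(4) scheme
#' (relative tolerance 1e-8, absolute 1e-10), reporting CoA, the biomass
#' production rate and integrated biomass on a dense output grid. CoA is
#' clamped at zero. The trajectory is classified into a regime:
#' \describe{
#'   \item{runaway}{CoA exceeds ten times its initial level at the end of the
#'     simulation while biomass production collapses below 10\% of its initial
#'     value (DCA-like toxicity).}
#'   \item{biphasic}{biomass production transiently rises at least 20\% above
#'     its initial value and ends at least 20\% below it (hopantenate-like:
#'     initial growth benefit, then CoA starvation).}
#'   \item{stable}{otherwise; the system relaxes to a fixed point where
#'     biosynthesis balances consumption.}
#' }
#'
#' @param params \code{coa_model_params}.
#' @param n_out Number of points of the output grid (default 2001).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class \code{coa_trajectory}: list with \code{trajectory}
#'   (data.frame time, coa, v_biomass, biomass), \code{regime} and
#'   \code{params}.
#' @export
simulate_coa <- function(params, n_out = 2001, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "coa_model_params"), params$t_end > 0)
  vc <- rate_v_coa(params)   # constant in CoA
  cpl <- params$coupling
  deriv <- function(t, y) {
    coa <- max(y[1], 0)
    vb <- rate_v_biomass(params, coa)
    c(vc - cpl * vb, vb * y[2])
  }
  times <- seq(0, params$t_end, length.out = n_out)
  sol <- ode_dopri(deriv, c(params$coa_0, params$biomass_0), times,
                   rtol = rtol, atol = atol)
  coa <- pmax(sol[, 1], 0)
  vb <- rate_v_biomass(params, coa)
  traj <- data.frame(time = times, coa = coa, v_biomass = vb,
                     biomass = sol[, 2])
  structure(list(trajectory = traj,
                 regime = classify_regime(traj, params),
                 params = params),
            class = "coa_trajectory")
}

#' Classify a simulated trajectory into a qualitative regime
#'
#' @param traj data.frame with columns \code{coa} and \code{v_biomass}.
#' @param params The \code{coa_model_params} used for the simulation.
#' @return One of \code{"runaway"}, \code{"biphasic"}, \code{"stable"}.
#' @export
classify_regime <- function(traj, params) {
  v0 <- traj$v_biomass[1]
  vend <- traj$v_biomass[nrow(traj)]
  cend <- traj$coa[nrow(traj)]
  if (cend > 10 * params$coa_0 && vend < 0.1 * v0) return("runaway")
  if (max(traj$v_biomass) > 1.2 * v0 && vend < 0.8 * v0) return("biphasic")
  "stable"
}

#' @export
print.coa_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("coa_trajectory: regime '%s'\n", x$regime))
  cat(sprintf("  t in [0, %g]; coa %g -> %g; v_biomass %g -> %g\n",
              max(tr$time), tr$coa[1], tr$coa[nrow(tr)],
              tr$v_biomass[1], tr$v_biomass[nrow(tr)]))
  invisible(x)
}

#' Simulate the standard perturbation scenarios
#'
#' Runs the model for untreated, DCA, hopantenate, DCA + hopantenate, and
#' exogenous-CoA conditions (initial CoA 10, 50, 100), reproducing the
#' qualitative panel set of the published figure: DCA drives runaway CoA
#' accumulation and growth arrest; hopantenate gives a biphasic response
#' (transient growth benefit, then CoA-limited growth); adding hopantenate to
#' DCA restores early-time growth above the DCA-only trajectory; raising
#' initial CoA depresses the initial biomass production rate
#' concentration-dependently.
#'
#' @param params Base \code{coa_model_params} (its \code{dca}, \code{hopan}
#'   and \code{coa_0} fields are overridden per scenario; defaults use
#'   \code{dca = 0.01} and \code{hopan = 5} for the treated scenarios).
#' @param dca Treated DCA concentration (default 0.01).
#' @param hopan Treated hopantenate concentration (default 5).
#' @return List with \code{regimes} (data.frame scenario, regime, plus
#'   initial/final summaries) and \code{trajectories} (named list of
#'   \code{coa_trajectory}).
#' @export
scenario_suite <- function(params = coa_model_params(), dca = 0.01, hopan = 5) {
  mod <- function(...) {
    upd <- list(...)
    p <- unclass(params)
    p[names(upd)] <- upd
    do.call(coa_model_params, p)
  }
  scen <- list(
    untreated = mod(dca = 0, hopan = 0),
    dca       = mod(dca = dca, hopan = 0),
    hopan     = mod(dca = 0, hopan = hopan),
    dca_hopan = mod(dca = dca, hopan = hopan),
    coa0_10   = mod(dca = 0, hopan = 0, coa_0 = 10),
    coa0_50   = mod(dca = 0, hopan = 0, coa_0 = 50),
    coa0_100  = mod(dca = 0, hopan = 0, coa_0 = 100)
  )
  trajs <- lapply(scen, simulate_coa)
  regimes <- data.frame(
    scenario = names(trajs),
    regime = vapply(trajs, `[[`, character(1), "regime"),
    v_biomass_0 = vapply(trajs, function(x) x$trajectory$v_biomass[1], numeric(1)),
    v_biomass_end = vapply(trajs, function(x) {
      tr <- x$trajectory; tr$v_biomass[nrow(tr)]
    }, numeric(1)),
    coa_end = vapply(trajs, function(x) {
      tr <- x$trajectory; tr$coa[nrow(tr)]
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(regimes) <- NULL
  list(regimes = regimes, trajectories = trajs)
}
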