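# Synthetic data with the statistical structure the pipeline assumes:
# intensities I = (alpha_line * N + beta) * exp(eps) with multiplicative
# lognormal noise, per-line exponential cell growth, drug-induced fold-change
# trajectories on chosen ions, and Hill-type dose-dependent growth inhibition.
# Ground truth is returned alongside every dataset, making the generator the
# validation harness for all estimation stages.

#' Configuration of the synthetic-data generator
#'
#' Defaults mirror the profiling study's design: 5 cell lines grown in
#' parallel, 3 replicate wells, sampling at 0/24/48/72/96 h, multiplicative
#' noise with 15\% coefficient of variation, and 9-dose grids for
#' dose-response experiments. Per-cell abundances (alpha) are drawn
#' log-uniformly, the shared MS background (beta) uniformly, and cell numbers
#' follow per-line exponential growth from the seeding density.
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_ions Number of non-background ions.
#' @param n_background_ions Ions with alpha = 0 in every line (pure MS
#'   background).
#' @param replicates Replicate wells per condition.
#' @param time_points_h Sampling times in hours.
#' @param alpha_range Log-uniform range of per-ion base per-cell intensities.
#' @param line_effect_range Log-uniform range of the per-(ion, line)
#'   modulation of the base abundance: metabolite levels differ between cell
#'   lines by a few fold, not by orders of magnitude.
#' @param beta_range Uniform range of background intensities.
#' @param n0_range Uniform range of seeded cell numbers per line.
#' @param growth_rate_range Uniform range of per-line growth rates (per hour).
#' @param carrying_cells Cell number corresponding to 100\% confluence.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_cell_lines = 5, n_ions = 50,
                             n_background_ions = 5, replicates = 3,
                             time_points_h = c(0, 24, 48, 72, 96),
                             alpha_range = c(0.5, 50),
                             line_effect_range = c(0.5, 2),
                             beta_range = c(2e3, 2e4),
                             n0_range = c(1.5e4, 4e4),
                             growth_rate_range = c(0.015, 0.03),
                             carrying_cells = 1e6,
                             noise_cv = 0.15,
                             seed = 1L) {
  stopifnot(n_cell_lines >= 1, n_ions >= 1, n_background_ions >= 0,
            replicates >= 1, all(alpha_range > 0), all(beta_range > 0),
            all(line_effect_range > 0), all(n0_range > 0),
            all(growth_rate_range > 0), noise_cv >= 0)
  structure(list(
    n_cell_lines = n_cell_lines, n_ions = n_ions,
    n_background_ions = n_background_ions, replicates = replicates,
    time_points_h = time_points_h, alpha_range = alpha_range,
    line_effect_range = line_effect_range,
    beta_range = beta_range, n0_range = n0_range,
    growth_rate_range = growth_rate_range, carrying_cells = carrying_cells,
    noise_cv = noise_cv, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# lognormal noise factors with E-free CV matching: sd of exp(eps) relative to
# its scale is cv when sigma^2 = log(1 + cv^2)
rlnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma))
}

# run expr with a local RNG state seeded deterministically
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Curated mini metabolite library plus random pseudo-metabolites
#'
#' Bundles a small library of real metabolites with correct sum formulas
#' (water, pyruvate and alpha-ketoglutarate flagged as alpha-keto acids,
#' lactate, pantothenate, coenzyme A, ATP, sedoheptulose 7-phosphate,
#' sorbitol, N-acetylaspartate, oxamate, citrate, glutamate) and appends
#' \code{n} random CHNOPS pseudo-formulas for scale.
#'
#' @param n Number of random pseudo-metabolites to append (default 0).
#' @param seed Seed for the pseudo-formula draw.
#' @return Metabolite table (see \code{\link{metabolite_table}}).
#' @export
generate_metabolite_library <- function(n = 0, seed = 1L) {
  curated <- data.frame(
    id = c("water", "pyruvate", "lactate", "pantothenate", "coa", "atp",
           "s7p", "sorbitol", "nacetylaspartate", "oxamate", "akg",
           "citrate", "glutamate"),
    name = c("Water", "Pyruvate", "L-Lactate", "Pantothenate", "Coenzyme A",
             "ATP", "Sedoheptulose 7-phosphate", "Sorbitol",
             "N-Acetylaspartate", "Oxamate", "2-Oxoglutarate", "Citrate",
             "Glutamate"),
    formula = c("H2O", "C3H4O3", "C3H6O3", "C9H17NO5", "C21H36N7O16P3S",
                "C10H16N5O13P3", "C7H15O10P", "C6H14O6", "C6H9NO5",
                "C2H3NO3", "C5H6O5", "C6H8O7", "C5H9NO4"),
    is_keto_acid = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, TRUE, FALSE, FALSE),
    source = "curated",
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    rand <- with_seed(seed, {
      data.frame(
        id = sprintf("pseudo%03d", seq_len(n)),
        name = sprintf("Pseudo metabolite %d", seq_len(n)),
        formula = sprintf("C%dH%dN%dO%d",
                          sample(3:30, n, replace = TRUE),
                          sample(4:50, n, replace = TRUE),
                          sample(0:6, n, replace = TRUE),
                          sample(1:12, n, replace = TRUE)),
        is_keto_acid = FALSE,
        source = "synthetic",
        stringsAsFactors = FALSE
      )
    })
    rand$formula <- vapply(rand$formula, function(f)
      formula_string(parse_formula(f)), character(1))
    curated <- rbind(curated, rand)
  }
  metabolite_table(curated)
}

#' Generate an unperturbed steady-state dataset
#'
#' Samples per-line per-cell abundances alpha (log-uniform; background ions
#' get alpha = 0 in every line), a shared background beta per ion, exponential
#' cell-number growth per line, and intensities
#' \code{I = (alpha * N + beta) * exp(eps)} with lognormal noise of the
#' configured CV. Confluence is cell number over carrying capacity.
#'
#' @param cfg \code{synthetic_config}.
#' @return List with \code{matrix} (ions x samples), \code{meta} (sample
#'   metadata data.frame) and \code{truth} (list with \code{alpha} matrix,
#'   \code{beta} vector, \code{growth_rate}, \code{n0}).
#' @export
generate_steady_state_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    lines <- sprintf("line%02d", seq_len(cfg$n_cell_lines))
    nion_t <- cfg$n_ions
    nion_b <- cfg$n_background_ions
    ions <- c(sprintf("ion%03d", seq_len(nion_t)),
              if (nion_b > 0) sprintf("bg%03d", seq_len(nion_b)))
    nion <- length(ions)

    base <- exp(stats::runif(nion_t, log(cfg$alpha_range[1]),
                             log(cfg$alpha_range[2])))
    line_eff <- matrix(exp(stats::runif(nion_t * cfg$n_cell_lines,
                                        log(cfg$line_effect_range[1]),
                                        log(cfg$line_effect_range[2]))),
                       nion_t, cfg$n_cell_lines)
    alpha <- base * line_eff
    alpha <- rbind(alpha, matrix(0, nion_b, cfg$n_cell_lines))
    dimnames(alpha) <- list(ions, lines)
    beta <- stats::setNames(stats::runif(nion, cfg$beta_range[1],
                                         cfg$beta_range[2]), ions)
    n0 <- stats::setNames(stats::runif(cfg$n_cell_lines, cfg$n0_range[1],
                                       cfg$n0_range[2]), lines)
    rate <- stats::setNames(stats::runif(cfg$n_cell_lines,
                                         cfg$growth_rate_range[1],
                                         cfg$growth_rate_range[2]), lines)

    meta <- expand.grid(replicate = seq_len(cfg$replicates),
                        time_h = cfg$time_points_h,
                        cell_line = lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # mild replicate-to-replicate seeding variability in cell numbers
    meta$cell_number <- n0[meta$cell_line] * exp(rate[meta$cell_line] * meta$time_h) *
      stats::runif(nrow(meta), 0.9, 1.1)
    meta$confluence <- pmin(meta$cell_number / cfg$carrying_cells, 1)
    meta$treatment <- "none"
    meta$sample_id <- sprintf("%s_t%03d_r%d_none", meta$cell_line,
                              meta$time_h, meta$replicate)
    meta <- meta[, c("sample_id", "cell_line", "replicate", "time_h",
                     "treatment", "cell_number", "confluence")]

    expected <- alpha[, meta$cell_line, drop = FALSE] *
      rep(meta$cell_number, each = nion) + beta
    mat <- expected * matrix(rlnoise(length(expected), cfg$noise_cv),
                             nrow = nion)
    dimnames(mat) <- list(ions, meta$sample_id)
    list(matrix = mat, meta = meta,
         truth = list(alpha = alpha, beta = beta, growth_rate = rate, n0 = n0))
  })
}

#' Generate a drug-perturbation dataset on top of a steady-state truth
#'
#' Treated intensities are
#' \code{I = (alpha * N + beta) * 2^fc_true * exp(eps)}: the unperturbed
#' expectation modulated by injected per-(ion, line, time) log2 fold-change
#' trajectories. Ions and lines not named in \code{effects} have
#' \code{fc_true = 0}. Injecting an effect on a background ion (alpha = 0) is
#' an error, as its fold-change against the cell-scaled baseline is undefined.
#'
#' @param cfg \code{synthetic_config} (replicates, time points, noise).
#' @param steady Output of \code{\link{generate_steady_state_dataset}} run on
#'   the same config.
#' @param effects data.frame with columns \code{ion}, \code{cell_line}
#'   (or "all"), \code{time_h} (or NA = all post-baseline times), \code{fc}.
#' @param treatment Treatment label for the generated samples (default "drug").
#' @param seed Seed; defaults to \code{cfg$seed + 1} so steady and treated
#'   noise are independent.
#' @return List with \code{matrix}, \code{meta} and \code{fc_true}
#'   (data.frame ion, cell_line, time_h, fc).
#' @export
generate_perturbation_dataset <- function(cfg, steady, effects,
                                          treatment = "drug",
                                          seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  alpha <- steady$truth$alpha
  beta <- steady$truth$beta
  ions <- rownames(alpha)
  lines <- colnames(alpha)
  times <- cfg$time_points_h
  if (nrow(effects) > 0) {
    stopifnot(all(c("ion", "cell_line", "fc") %in% names(effects)))
    if (!all(effects$ion %in% ions)) stop("effect on unknown ion")
    bg <- effects$ion[rowSums(alpha[effects$ion, , drop = FALSE] > 0) == 0]
    if (length(bg)) {
      stop(sprintf("effect injected on background ion '%s': baseline undefined", bg[1]))
    }
  }

  # expand effects to a dense fc_true grid (ion x line x time), default 0
  grid <- expand.grid(ion = ions, cell_line = lines, time_h = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$fc <- 0
  if (nrow(effects) > 0) {
    if (is.null(effects$time_h)) effects$time_h <- NA
    for (r in seq_len(nrow(effects))) {
      e <- effects[r, ]
      sel <- grid$ion == e$ion &
        (e$cell_line == "all" | grid$cell_line == e$cell_line) &
        (is.na(e$time_h) & grid$time_h > 0 |
           !is.na(e$time_h) & grid$time_h == e$time_h)
      grid$fc[sel] <- e$fc
    }
  }

  with_seed(seed, {
    meta <- expand.grid(replicate = seq_len(cfg$replicates),
                        time_h = times, cell_line = lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rate <- steady$truth$growth_rate
    n0 <- steady$truth$n0
    meta$cell_number <- n0[meta$cell_line] *
      exp(rate[meta$cell_line] * meta$time_h) *
      stats::runif(nrow(meta), 0.9, 1.1)
    meta$confluence <- pmin(meta$cell_number / cfg$carrying_cells, 1)
    meta$treatment <- treatment
    meta$sample_id <- sprintf("%s_t%03d_r%d_%s", meta$cell_line, meta$time_h,
                              meta$replicate, treatment)
    meta <- meta[, c("sample_id", "cell_line", "replicate", "time_h",
                     "treatment", "cell_number", "confluence")]

    nion <- length(ions)
    expected <- alpha[, meta$cell_line, drop = FALSE] *
      rep(meta$cell_number, each = nion) + beta
    fc_idx <- match(paste(rep(ions, times = nrow(meta)),
                          rep(meta$cell_line, each = nion),
                          rep(meta$time_h, each = nion)),
                    paste(grid$ion, grid$cell_line, grid$time_h))
    fcmat <- matrix(grid$fc[fc_idx], nrow = nion)
    mat <- expected * 2^fcmat *
      matrix(rlnoise(length(expected), cfg$noise_cv), nrow = nion)
    dimnames(mat) <- list(ions, meta$sample_id)
    list(matrix = mat, meta = meta, fc_true = grid)
  })
}

#' Generate dose-response confluence curves
#'
#' Confluence grows exponentially at the untreated rate scaled by
#' \code{1 - inhibition(dose)} with Hill-type inhibition
#' \code{1 / (1 + (gi50 / d)^h)}, multiplied by lognormal noise and truncated
#' at full confluence.
#'
#' @param doses Dose grid including 0 (default: 0 plus 9 half-log steps
#'   around the GI50, mirroring a 9-concentration design).
#' @param gi50 True GI50 (mM).
#' @param hill Hill slope.
#' @param rate Untreated growth rate (per hour).
#' @param c0 Seeding confluence.
#' @param times Measurement times in hours (default 0/24/48/72).
#' @param replicates Replicate wells per dose.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Seed.
#' @return data.frame \code{time_h}, \code{dose}, \code{replicate},
#'   \code{confluence}, with the true inhibition per dose in attribute
#'   \code{"inhibition_true"}.
#' @export
generate_growth_curves <- function(doses = NULL, gi50 = 12, hill = 2,
                                   rate = 0.03, c0 = 0.05,
                                   times = c(0, 24, 48, 72),
                                   replicates = 3, noise_cv = 0,
                                   seed = 1L) {
  stopifnot(gi50 > 0, rate > 0, c0 > 0)
  if (is.null(doses)) doses <- c(0, gi50 * 10^seq(-2, 2, length.out = 9))
  inh <- ifelse(doses == 0, 0, 1 / (1 + (gi50 / doses)^hill))
  with_seed(seed, {
    df <- expand.grid(time_h = times, dose = doses,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
    df$confluence <- pmin(
      c0 * exp(rate * (1 - inh[match(df$dose, doses)]) * df$time_h) *
        rlnoise(nrow(df), noise_cv), 1)
    df <- df[order(df$dose, df$time_h, df$replicate), ]
    rownames(df) <- NULL
    attr(df, "inhibition_true") <- stats::setNames(inh, doses)
    df
  })
}
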