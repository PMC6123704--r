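# Shared linear intensity model across cell lines.

make_meta <- function(lines, N_per_line, confluence = 0.5) {
  meta <- data.frame(
    cell_line = rep(lines, each = length(N_per_line[[1]])),
    cell_number = unlist(N_per_line),
    stringsAsFactors = FALSE
  )
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  meta$replicate <- 1L
  meta$time_h <- 0
  meta$treatment <- "none"
  meta$confluence <- confluence
  meta
}

test_that("confluence filter removes samples above the threshold", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     confluence = c(0.5, 0.79, 0.81))
  expect_equal(filter_by_confluence(meta)$sample_id, c("a", "b"))
  meta$confluence <- c(0.1, 0.5, 0.8)  # boundary 0.80 is kept ("above" excluded)
  expect_equal(nrow(filter_by_confluence(meta)), 3L)
  meta$confluence <- c(0.9, 0.95, 1.0)
  expect_warning(out <- filter_by_confluence(meta), "all samples")
  expect_equal(nrow(out), 0L)
})

test_that("noiseless two-line data recover alpha and beta exactly", {
  meta <- make_meta(c("A", "B"), list(seq(1000, 5000, 1000), seq(1000, 5000, 1000)))
  I <- ifelse(meta$cell_line == "A", 100, 200) * meta$cell_number + 50
  f <- fit_ion(I, meta)
  expect_equal(unname(f$alpha), c(100, 200), tolerance = 1e-6)
  expect_equal(f$beta, 50, tolerance = 1e-6 * 50)
  expect_lt(max(f$alpha_p), 1e-10)
})

test_that("background-only ion yields alpha near 0 with large p", {
  set.seed(5)
  meta <- make_meta(c("A", "B"), list(seq(1000, 8000, 1000), seq(1000, 8000, 1000)))
  I <- 500 + rnorm(nrow(meta), 0, 5)  # flat: no cell-number dependence
  f <- fit_ion(I, meta)
  expect_lt(max(abs(f$alpha)), 0.01)
  expect_gt(min(f$alpha_p), 0.05)
  expect_equal(f$beta, 500, tolerance = 0.05)
})

test_that("fitter equals the normal-equations oracle and scales equivariantly", {
  set.seed(9)
  meta <- make_meta(c("A", "B", "C"),
                    list(runif(8, 1e3, 1e4), runif(8, 1e3, 1e4), runif(8, 1e3, 1e4)))
  alpha <- c(A = 3, B = 11, C = 0.7)
  I <- alpha[meta$cell_line] * meta$cell_number + 800
  I <- I * exp(rnorm(length(I), 0, 0.1))
  f <- fit_ion(I, meta)
  X <- cbind(vapply(c("A", "B", "C"),
                    function(l) ifelse(meta$cell_line == l, meta$cell_number, 0),
                    numeric(nrow(meta))), 1)
  ref <- normal_equations_fit(X, I)
  expect_equal(unname(c(f$alpha, f$beta)), unname(ref), tolerance = 1e-8)

  # multiplying intensities by c scales coefficients by c, p-values unchanged
  f10 <- fit_ion(10 * I, meta)
  expect_equal(unname(f10$alpha), unname(10 * f$alpha), tolerance = 1e-9)
  expect_equal(f10$beta, 10 * f$beta, tolerance = 1e-9 * abs(f$beta) * 10)
  expect_equal(f10$alpha_p, f$alpha_p, tolerance = 1e-9)
})

test_that("batched fit_all equals per-ion fit_ion and flags background ions", {
  cfg <- synthetic_config(n_cell_lines = 3, n_ions = 7, n_background_ions = 3,
                          noise_cv = 0.15, seed = 21)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  # batched path must agree with the scalar path
  i <- "ion003"
  f1 <- fit_ion(ss$matrix[i, ], ss$meta)
  expect_equal(unname(fit$alpha[i, ]), unname(f1$alpha), tolerance = 1e-10)
  expect_equal(unname(fit$alpha_p[i, ]), unname(f1$alpha_p), tolerance = 1e-8)
  expect_equal(unname(fit$beta[[i]]), f1$beta, tolerance = 1e-10)
  # 7 real ions reliable somewhere, 3 background ions excluded
  expect_equal(sum(!fit$excluded), 7L)
  expect_true(all(fit$excluded[paste0("bg00", 1:3)]))
  # missing values force the per-ion path; results still consistent
  m2 <- ss$matrix
  m2[2, 5] <- NA
  fit2 <- fit_all(m2, ss$meta)
  expect_equal(unname(fit2$alpha[1, ]), unname(fit$alpha[1, ]), tolerance = 1e-10)
  expect_equal(unname(fit2$n_used[[2]]), ncol(m2) - 1)
})

test_that("reliability is monotone in the p threshold and edge cases work", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 20, n_background_ions = 5,
                          noise_cv = 0.2, seed = 31)
  ss <- generate_steady_state_dataset(cfg)
  f_strict <- fit_all(ss$matrix, ss$meta, p_threshold = 1e-4)
  f_loose <- fit_all(ss$matrix, ss$meta, p_threshold = 0.01)
  expect_true(all(f_loose$reliable[f_strict$reliable]))
  # p_threshold = 1 with positive alpha: everything estimable is reliable
  f_all <- fit_all(ss$matrix, ss$meta, p_threshold = 1)
  expect_true(all(f_all$reliable[f_all$alpha > 0]))
  # single cell line reduces to simple regression
  one <- ss$meta$cell_line == "line01"
  f1 <- fit_all(ss$matrix[, one, drop = FALSE], ss$meta[one, ])
  lmref <- lm(ss$matrix[1, one] ~ ss$meta$cell_number[one])
  expect_equal(unname(f1$alpha[1, 1]), unname(coef(lmref)[2]), tolerance = 1e-8)
})

test_that("alpha estimates fall within 3 SE at the expected rate under noise", {
  # 400 replicate ions of one true (alpha, beta) config, 2 lines x 8 samples
  set.seed(77)
  meta <- make_meta(c("A", "B"), list(seq(1e3, 8e3, 1e3), seq(1e3, 8e3, 1e3)))
  alpha <- c(A = 50, B = 120); beta <- 3000
  expected <- alpha[meta$cell_line] * meta$cell_number + beta
  sigma <- sqrt(log(1 + 0.15^2))
  mat <- t(vapply(1:400, function(i) expected * exp(rnorm(length(expected), 0, sigma)),
                  numeric(nrow(meta))))
  rownames(mat) <- sprintf("ion%03d", 1:400)
  colnames(mat) <- meta$sample_id
  fit <- fit_all(mat, meta)
  cover <- abs(sweep(fit$alpha, 2, alpha, `-`)) <= 3 * fit$alpha_se
  expect_gte(mean(cover), 0.95)
})

test_that("median CV summary and per-sample abundances behave", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 10, n_background_ions = 0,
                          noise_cv = 0, seed = 3)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  expect_lt(summarize_cv(fit), 1e-6)  # noiseless: ~0%
  ab <- per_sample_abundance(ss$matrix, ss$meta, fit)
  expect_equal(unname(ab[, 1]), unname(ss$truth$alpha[, ss$meta$cell_line[1]]),
               tolerance = 1e-6)
  # synthetic CVs median: {0.1, 0.2, 0.4} -> 20%
  fit$cv[] <- NA; fit$reliable[] <- FALSE
  fit$cv[1, 1] <- 0.1; fit$cv[2, 1] <- 0.2; fit$cv[3, 1] <- 0.4
  fit$reliable[1:3, 1] <- TRUE
  expect_equal(summarize_cv(fit), 20)
  fit$reliable[] <- FALSE
  expect_error(summarize_cv(fit), "no reliable")
})

test_that("one-way ANOVA across lines detects differences and stays calibrated", {
  # identical group means with tiny within-group spread: F = 0, p = 1
  ab <- matrix(c(1, 1.001, 0.999, 1.0005, 0.9995, 1), nrow = 1)
  colnames(ab) <- sprintf("s%d", 1:6)
  lines <- rep(c("A", "B"), each = 3)
  res0 <- anova_across_lines(ab, lines)
  expect_lt(res0$F, 1e-6)
  expect_gt(res0$p, 0.99)

  set.seed(13)
  ab1 <- matrix(c(1, 1, 1, 2, 2, 2) + rnorm(6, 0, 1e-4), nrow = 1)
  expect_lt(anova_across_lines(ab1, lines)$p, 1e-4)

  # null simulation: ~5% raw p < 0.05, ~none significant after BH
  nulls <- matrix(rnorm(100 * 6), nrow = 100)
  res <- anova_across_lines(nulls, lines)
  expect_lt(mean(res$p < 0.05), 0.12)
  expect_equal(sum(res$significant), 0L)
})
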