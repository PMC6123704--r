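# Fold-changes against the model-predicted unperturbed baseline.

test_that("predict_baseline is alpha * N + beta for reliable pairs", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 4, n_background_ions = 1,
                          noise_cv = 0, seed = 17)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  a <- fit$alpha["ion001", "line01"]; b <- fit$beta[["ion001"]]
  expect_equal(predict_baseline(fit, "ion001", "line01", 0), b)
  expect_equal(predict_baseline(fit, "ion001", "line01", 10), a * 10 + b)
  # model self-consistency: noiseless unperturbed data predict themselves
  s1 <- ss$meta$sample_id[1]
  expect_equal(predict_baseline(fit, "ion001", ss$meta$cell_line[1],
                                ss$meta$cell_number[1]),
               unname(ss$matrix["ion001", s1]), tolerance = 1e-9)
  expect_warning(v <- predict_baseline(fit, "bg001", "line01", 10), "not reliable")
  expect_true(is.na(v))
  expect_error(predict_baseline(fit, "nope", "line01", 1), "unknown ion")
})

test_that("fold-change significance follows the one-sample t-test", {
  expect_equal(fold_change_significance(c(0, 0, 0)), 1)
  # closed form: mean 2, sd 0.1, n 3 -> t = 34.64, df = 2
  p <- 2 * pt(-2 / (0.1 / sqrt(3)), df = 2)
  expect_equal(fold_change_significance(c(2.0, 2.1, 1.9)), p, tolerance = 1e-12)
  expect_lt(p, 0.01)
  expect_true(is.na(fold_change_significance(2.0)))
  # calibration: type-I error ~5% at p < 0.05 (exact t under normal noise)
  set.seed(19)
  ps <- replicate(1000, fold_change_significance(rnorm(3, 0, 0.3)))
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.4)  # binomial SE ~ 0.007
})

test_that("fold changes recover exact ratios and injected effects", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 6, n_background_ions = 0,
                          replicates = 3, noise_cv = 0, seed = 23)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)

  # treated == baseline -> fc = 0; treated = 2x baseline -> fc = 1
  pert0 <- generate_perturbation_dataset(cfg, ss, effects = data.frame(
    ion = character(0), cell_line = character(0), fc = numeric(0)))
  fc0 <- compute_fold_changes(pert0$matrix, pert0$meta, fit)
  expect_lt(max(abs(fc0$log2fc)), 1e-9)

  eff <- data.frame(ion = c("ion001", "ion002"), cell_line = "all",
                    time_h = NA, fc = c(1, -2))
  pert <- generate_perturbation_dataset(cfg, ss, eff)
  fc <- compute_fold_changes(pert$matrix, pert$meta, fit)
  post <- fc[fc$time_h > 0, ]
  expect_equal(unique(round(post$log2fc[post$ion == "ion001"], 9)), 1)
  expect_equal(unique(round(post$log2fc[post$ion == "ion002"], 9)), -2)
  expect_equal(unique(round(post$log2fc[post$ion == "ion003"], 9)), 0)

  # 4-fold depletion under 15% noise comes back as ~ -2
  cfgn <- synthetic_config(n_cell_lines = 2, n_ions = 6, n_background_ions = 0,
                           replicates = 3, noise_cv = 0.15, seed = 29)
  ssn <- generate_steady_state_dataset(cfgn)
  fitn <- fit_all(ssn$matrix, ssn$meta)
  pn <- generate_perturbation_dataset(cfgn, ssn, data.frame(
    ion = "ion001", cell_line = "all", time_h = NA, fc = -2))
  fcn <- compute_fold_changes(pn$matrix, pn$meta, fitn)
  got <- fcn$log2fc[fcn$ion == "ion001" & fcn$time_h > 0]
  expect_equal(mean(got), -2, tolerance = 0.15)
})

test_that("fc is monotone in intensity and in cell number", {
  cfg <- synthetic_config(n_cell_lines = 1, n_ions = 2, n_background_ions = 0,
                          noise_cv = 0, seed = 41)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  a <- fit$alpha[1, 1]; b <- fit$beta[[1]]
  I <- seq(b + 10, b + 1e5, length.out = 20)
  fcs <- log2(I / (a * 1e4 + b))
  expect_true(all(diff(fcs) > 0))
  Ns <- seq(1e3, 1e5, length.out = 20)
  fcN <- log2(5e4 / (a * Ns + b))
  expect_true(all(diff(fcN) < 0))
})

test_that("invalid replicates are dropped and logged as reduced n_reps", {
  cfg <- synthetic_config(n_cell_lines = 1, n_ions = 2, n_background_ions = 0,
                          replicates = 3, time_points_h = c(0, 24),
                          noise_cv = 0, seed = 43)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  pert <- generate_perturbation_dataset(cfg, ss, effects = data.frame(
    ion = character(0), cell_line = character(0), fc = numeric(0)))
  m <- pert$matrix
  m[1, 1] <- 0        # non-positive intensity -> replicate dropped
  m[2, 2] <- NA       # missing -> dropped
  fc <- compute_fold_changes(m, pert$meta, fit)
  t1 <- pert$meta$time_h[match(colnames(m)[1:2], pert$meta$sample_id)]
  expect_equal(fc$n_reps[fc$ion == rownames(m)[1] & fc$time_h == t1[1]], 2)
  expect_equal(fc$n_reps[fc$ion == rownames(m)[2] & fc$time_h == t1[2]], 2)
})

test_that("null pipeline centers fold-changes near zero", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 60, n_background_ions = 0,
                          replicates = 6, noise_cv = 0.15, seed = 47)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  pert <- generate_perturbation_dataset(cfg, ss, effects = data.frame(
    ion = character(0), cell_line = character(0), fc = numeric(0)))
  fc <- compute_fold_changes(pert$matrix, pert$meta, fit)
  expect_lt(abs(median(fc$log2fc)), 0.05)
})

test_that("two-sample mode tests treated against time-matched untreated wells", {
  cfg <- synthetic_config(n_cell_lines = 2, n_ions = 4, n_background_ions = 0,
                          replicates = 4, noise_cv = 0.1, seed = 53)
  ss <- generate_steady_state_dataset(cfg)
  fit <- fit_all(ss$matrix, ss$meta)
  pert <- generate_perturbation_dataset(cfg, ss, data.frame(
    ion = "ion001", cell_line = "all", time_h = NA, fc = 3), treatment = "DCA")
  both_mat <- cbind(ss$matrix, pert$matrix)
  both_meta <- rbind(ss$meta, pert$meta)
  fc2 <- compute_fold_changes(both_mat, both_meta, fit, test = "two-sample")
  hit <- fc2[fc2$ion == "ion001" & fc2$treatment == "DCA" & fc2$time_h > 0, ]
  miss <- fc2[fc2$ion == "ion002" & fc2$treatment == "DCA" & fc2$time_h > 0, ]
  expect_true(all(hit$pvalue < 0.01))
  expect_gt(mean(miss$pvalue > 0.05), 0.7)
  expect_true(all(is.na(fc2$pvalue[fc2$treatment == "none"])))
})
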