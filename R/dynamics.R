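# Time-resolved drug-induced log2 fold-changes against the model-predicted
# unperturbed baseline: FC = log2( I / (alpha * N + beta) ) per replicate,
# with per-(ion, line, treatment, time) one-sample t-tests.

#' Model-predicted unperturbed baseline intensity
#'
#' The expected intensity of an ion in an unperturbed culture of a given cell
#' line at a given extracted cell number: \code{alpha_line * N + beta}. Only
#' defined for (ion, line) pairs that passed the reliability filter.
#'
#' @param fit A \code{steady_state_fit}.
#' @param ion Ion id (rowname in the fit).
#' @param cell_line Cell line name.
#' @param N Extracted cell number(s).
#' @return Predicted intensity (NA with a warning if the pair is unreliable).
#' @export
predict_baseline <- function(fit, ion, cell_line, N) {
  stopifnot(inherits(fit, "steady_state_fit"))
  if (!ion %in% rownames(fit$alpha)) stop(sprintf("unknown ion '%s'", ion))
  if (!cell_line %in% colnames(fit$alpha)) {
    stop(sprintf("unknown cell line '%s'", cell_line))
  }
  if (!isTRUE(fit$reliable[ion, cell_line])) {
    warning(sprintf("ion '%s' is not reliable in cell line '%s'; baseline undefined",
                    ion, cell_line))
    return(rep(NA_real_, length(N)))
  }
  unname(fit$alpha[ion, cell_line] * N + fit$beta[[ion]])
}

# one-sample two-sided t-test of x against 0, with the zero-statistic
# convention p = 1 when all values equal 0 (p = 0 for constant non-zero x).
t_test_p <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(if (m == 0) 1 else 0)
  2 * stats::pt(-abs(m / (s / sqrt(n))), df = n - 1)
}

#' Significance of replicate log2 fold-changes
#'
#' Two-sided one-sample t-test of the replicate log2 fold-changes against 0.
#' With fewer than two replicates the p-value is undefined (NA). All-zero
#' replicates return p = 1 by the zero-statistic convention.
#'
#' @param fcs Numeric vector of replicate log2 fold-changes.
#' @return p-value.
#' @export
fold_change_significance <- function(fcs) t_test_p(fcs)

#' Drug-induced log2 fold-changes against the model baseline
#'
#' For every treated sample, the replicate-level fold-change is
#' \code{log2(I / (alpha * N + beta))} with alpha, beta from the steady-state
#' fit and N the extracted cell number at sampling time. Replicates are
#' aggregated per (ion, cell line, treatment, time point) by the arithmetic
#' mean on the log2 scale, and significance is a two-sided one-sample t-test
#' of the replicate values against zero (default) or a Welch two-sample test
#' against time-matched untreated samples (\code{test = "two-sample"};
#' requires samples with \code{treatment == "none"}).
#'
#' Replicates with non-positive measured intensity or non-positive predicted
#' baseline are dropped. (Ion, line) pairs that failed the reliability filter
#' are excluded.
#'
#' @param mat Treated intensity matrix (ions x samples).
#' @param meta Sample metadata with \code{sample_id}, \code{cell_line},
#'   \code{treatment}, \code{time_h}, \code{cell_number}.
#' @param fit A \code{steady_state_fit} covering the same ions.
#' @param test \code{"one-sample"} (default) or \code{"two-sample"}.
#' @param keep_replicates If TRUE, attach the replicate-level long table as
#'   attribute \code{"replicates"}.
#' @return data.frame \code{ion}, \code{cell_line}, \code{treatment},
#'   \code{time_h}, \code{log2fc}, \code{pvalue}, \code{n_reps},
#'   \code{baseline} (mean predicted baseline of used replicates).
#' @export
compute_fold_changes <- function(mat, meta, fit,
                                 test = c("one-sample", "two-sample"),
                                 keep_replicates = FALSE) {
  test <- match.arg(test)
  stopifnot(is.matrix(mat), inherits(fit, "steady_state_fit"))
  meta <- as.data.frame(meta)
  if (!all(colnames(mat) %in% meta$sample_id)) {
    stop(sprintf("sample column '%s' absent from metadata",
                 setdiff(colnames(mat), meta$sample_id)[1]))
  }
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  ions <- rownames(mat)
  if (is.null(ions)) stop("intensity matrix must have ion rownames")
  if (!all(ions %in% rownames(fit$alpha))) {
    stop("fit does not cover all ions in the matrix")
  }
  lines <- as.character(meta$cell_line)
  if (!all(unique(lines) %in% colnames(fit$alpha))) {
    stop("fit does not cover all cell lines in the metadata")
  }

  # replicate-level fc matrix (ions x samples)
  A <- fit$alpha[ions, lines, drop = FALSE]            # ions x samples
  baseline <- sweep(A * rep(meta$cell_number, each = length(ions)),
                    1, fit$beta[ions], `+`)
  rel <- fit$reliable[ions, lines, drop = FALSE]
  valid <- rel & !is.na(mat) & mat > 0 & !is.na(baseline) & baseline > 0
  fcrep <- matrix(NA_real_, nrow(mat), ncol(mat))
  fcrep[valid] <- log2(mat[valid] / baseline[valid])
  baseline[!valid] <- NA_real_

  grp <- interaction(lines, as.character(meta$treatment), meta$time_h,
                     drop = TRUE, sep = "\r")
  gl <- levels(grp)
  gmat <- t(vapply(gl, function(g) grp == g, logical(length(grp))))  # groups x samples

  agg <- function(M, G) {
    # per-group row statistics over non-NA entries; returns list of ion x group
    ok <- !is.na(M)
    M0 <- ifelse(ok, M, 0)
    n <- ok %*% t(G)
    s1 <- M0 %*% t(G)
    s2 <- (M0^2) %*% t(G)
    mean <- ifelse(n > 0, s1 / n, NA_real_)
    var <- ifelse(n > 1, pmax(s2 - n * mean^2, 0) / (n - 1), NA_real_)
    list(n = n, mean = mean, var = var)
  }
  st <- agg(fcrep, gmat * 1)
  bl <- agg(baseline, gmat * 1)

  parts <- do.call(rbind, strsplit(gl, "\r", fixed = TRUE))
  ngrp <- length(gl)
  nion <- length(ions)
  out <- data.frame(
    ion = rep(ions, times = ngrp),
    cell_line = rep(parts[, 1], each = nion),
    treatment = rep(parts[, 2], each = nion),
    time_h = rep(as.numeric(parts[, 3]), each = nion),
    log2fc = as.vector(st$mean),
    pvalue = NA_real_,
    n_reps = as.vector(st$n),
    baseline = as.vector(bl$mean),
    stringsAsFactors = FALSE
  )

  # one-sample t against 0 (vectorized over the ion x group grids)
  testable <- !is.na(st$var) & st$var > 0 & st$n >= 2
  tt <- ifelse(testable, st$mean / sqrt(st$var / st$n), 0)
  p1 <- matrix(NA_real_, nrow(tt), ncol(tt))
  p1[testable] <- 2 * stats::pt(-abs(tt[testable]), df = st$n[testable] - 1)
  zerovar <- !is.na(st$var) & st$var == 0 & st$n >= 2
  p1[zerovar] <- ifelse(st$mean[zerovar] == 0, 1, 0)

  if (test == "one-sample") {
    out$pvalue <- as.vector(p1)
  } else {
    # Welch test of treated replicate fcs vs time-matched untreated fcs
    key <- paste(parts[, 1], parts[, 3], sep = "\r")
    untreated <- parts[, 2] == "none"
    ref_idx <- match(key, key[untreated])
    pw <- matrix(NA_real_, nion, ngrp)
    for (j in seq_len(ngrp)) {
      if (untreated[j] || is.na(ref_idx[j])) next
      r <- which(untreated)[ref_idx[j]]
      n1 <- st$n[, j]; n2 <- st$n[, r]
      v1 <- st$var[, j] / n1; v2 <- st$var[, r] / n2
      tw <- (st$mean[, j] - st$mean[, r]) / sqrt(v1 + v2)
      dfw <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
      pw[, j] <- ifelse(n1 >= 2 & n2 >= 2, 2 * stats::pt(-abs(tw), dfw), NA_real_)
    }
    out$pvalue <- as.vector(pw)
  }

  out <- out[out$n_reps > 0, , drop = FALSE]
  out <- out[order(out$ion, out$cell_line, out$treatment, out$time_h), ]
  rownames(out) <- NULL
  if (keep_replicates) {
    reps <- data.frame(
      ion = rep(ions, times = ncol(mat)),
      sample_id = rep(meta$sample_id, each = nion),
      cell_line = rep(lines, each = nion),
      treatment = rep(as.character(meta$treatment), each = nion),
      time_h = rep(meta$time_h, each = nion),
      log2fc = as.vector(fcrep),
      stringsAsFactors = FALSE
    )
    attr(out, "replicates") <- reps[!is.na(reps$log2fc), ]
  }
  out
}
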