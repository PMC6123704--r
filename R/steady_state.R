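# Shared linear intensity model: I = alpha_line * N_c + beta, fitted jointly
# across cell lines per ion, with per-coefficient F-tests and the
# "alpha > 0, p <= 0.001 in at least one line" reliability filter.

#' Exclude samples above the confluence validity threshold
#'
#' Extracted cell numbers cannot be derived reliably from bright-field images
#' above ~80\% confluence, and cells deviate from metabolic steady state, so
#' such samples are excluded from baseline model fitting.
#'
#' @param meta Sample metadata data.frame with a \code{confluence} column
#'   (fraction in [0, 1]).
#' @param max_confluence Threshold; samples with confluence strictly above it
#'   are removed (default 0.80).
#' @return Filtered metadata, original order preserved.
#' @export
filter_by_confluence <- function(meta, max_confluence = 0.80) {
  stopifnot(is.data.frame(meta), "confluence" %in% names(meta))
  if (anyNA(meta$confluence)) stop("confluence missing for some samples")
  keep <- meta$confluence <= max_confluence
  if (!any(keep)) {
    warning("all samples exceed the confluence threshold; returning empty set")
  }
  meta[keep, , drop = FALSE]
}

# ordinary least squares with pivoted QR; returns NA for non-estimable
# coefficients. Independent of lm() bookkeeping but numerically identical.
ols_fit <- function(X, y) {
  qx <- qr(X)
  r <- qx$rank
  p <- ncol(X)
  coef <- qr.coef(qx, y)            # NA for aliased columns
  fitted <- qr.fitted(qx, y)
  resid <- y - fitted
  df <- length(y) - r
  sigma2 <- if (df > 0) sum(resid^2) / df else NA_real_
  se <- rep(NA_real_, p)
  if (df > 0 && r > 0) {
    piv <- qx$pivot[seq_len(r)]
    R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    XtXinv <- chol2inv(R)
    se[piv] <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  }
  names(se) <- colnames(X)
  list(coef = coef, se = se, df = df, sigma2 = sigma2, rank = r)
}

#' Fit the shared intensity model for one ion
#'
#' Solves the multi-cell-line linear model in which the measured intensity of
#' an ion is \code{alpha_line * N_c} plus a background offset \code{beta}
#' shared across all cell lines (the MS background does not depend on cell
#' type). Each coefficient is tested against zero with the F statistic of the
#' least-squares fit (equivalent to the squared t statistic for a single
#' coefficient).
#'
#' @param intensity Numeric vector of measured intensities, one per sample
#'   (NA allowed; such samples are dropped for this ion).
#' @param meta Sample metadata with columns \code{cell_line} and
#'   \code{cell_number}, rows aligned with \code{intensity}.
#' @return List with \code{alpha}, \code{alpha_se}, \code{alpha_p} (named by
#'   cell line; NA where non-estimable), \code{beta}, \code{beta_se},
#'   \code{beta_p}, \code{df} and \code{n_used}.
#' @export
fit_ion <- function(intensity, meta) {
  stopifnot(length(intensity) == nrow(meta))
  lines <- as.character(meta$cell_line)
  ulines <- sort(unique(lines))
  ok <- !is.na(intensity) & !is.na(meta$cell_number)
  if (sum(ok) == 0L) stop("all intensities missing for this ion")
  y <- intensity[ok]
  ln <- lines[ok]
  N <- meta$cell_number[ok]
  X <- cbind(
    vapply(ulines, function(l) ifelse(ln == l, N, 0), numeric(length(y))),
    beta = 1
  )
  colnames(X) <- c(ulines, "beta")
  fit <- ols_fit(X, y)
  tval <- fit$coef / fit$se
  pval <- if (fit$df > 0) stats::pf(tval^2, 1, fit$df, lower.tail = FALSE)
          else rep(NA_real_, length(tval))
  k <- length(ulines)
  list(
    alpha    = stats::setNames(fit$coef[seq_len(k)], ulines),
    alpha_se = stats::setNames(fit$se[seq_len(k)], ulines),
    alpha_p  = stats::setNames(pval[seq_len(k)], ulines),
    beta     = unname(fit$coef[k + 1L]),
    beta_se  = unname(fit$se[k + 1L]),
    beta_p   = unname(pval[k + 1L]),
    df       = fit$df,
    n_used   = length(y)
  )
}

#' Fit the shared intensity model for every ion
#'
#' Applies \code{\link{fit_ion}} to each row of the intensity matrix. When the
#' matrix is complete (no missing values) all ions share one design matrix and
#' the fit is computed in a single batched linear solve. A cell line is
#' flagged \emph{reliable} for an ion when its estimated per-cell abundance is
#' positive and the coefficient p-value is at or below \code{p_threshold};
#' ions with no reliable line are flagged excluded (background or
#' below-detection-limit ions).
#'
#' @param mat Numeric matrix, ions in rows (rownames = ion ids), samples in
#'   columns (colnames = sample ids).
#' @param meta Sample metadata data.frame with \code{sample_id},
#'   \code{cell_line}, \code{cell_number}; rows must cover all columns of
#'   \code{mat}.
#' @param p_threshold Reliability p-value cutoff (default 0.001).
#' @param max_confluence If non-NULL and \code{meta} has a confluence column,
#'   samples above this confluence are excluded before fitting (default 0.80).
#' @return Object of class \code{steady_state_fit}: list with matrices
#'   \code{alpha}, \code{alpha_se}, \code{alpha_p}, \code{cv},
#'   \code{reliable} (ions x lines), vectors \code{beta}, \code{beta_se},
#'   \code{n_used}, logical \code{excluded}, and the threshold used.
#' @export
fit_all <- function(mat, meta, p_threshold = 0.001, max_confluence = 0.80) {
  stopifnot(is.matrix(mat), nrow(mat) > 0L)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("ion", seq_len(nrow(mat)))
  meta <- as.data.frame(meta)
  if (!all(colnames(mat) %in% meta$sample_id)) {
    missing <- setdiff(colnames(mat), meta$sample_id)
    stop(sprintf("sample column '%s' absent from metadata", missing[1]))
  }
  if (!is.null(max_confluence) && "confluence" %in% names(meta)) {
    meta <- filter_by_confluence(meta, max_confluence)
  }
  meta <- meta[match(intersect(colnames(mat), meta$sample_id), meta$sample_id), ]
  mat <- mat[, meta$sample_id, drop = FALSE]

  ulines <- sort(unique(as.character(meta$cell_line)))
  k <- length(ulines)
  nion <- nrow(mat)
  alpha <- alpha_se <- alpha_p <- matrix(
    NA_real_, nion, k, dimnames = list(rownames(mat), ulines))
  beta <- beta_se <- n_used <- stats::setNames(rep(NA_real_, nion), rownames(mat))

  complete <- !anyNA(mat)
  if (complete) {
    # batched solve: one shared design for all ions
    N <- meta$cell_number
    ln <- as.character(meta$cell_line)
    X <- cbind(vapply(ulines, function(l) ifelse(ln == l, N, 0),
                      numeric(nrow(meta))), beta = 1)
    colnames(X) <- c(ulines, "beta")
    qx <- qr(X)
    if (qx$rank == ncol(X)) {
      coefs <- t(qr.coef(qx, t(mat)))                      # ions x (k+1)
      fittedv <- coefs %*% t(X)
      rss <- rowSums((mat - fittedv)^2)
      df <- nrow(meta) - ncol(X)
      sigma2 <- rss / df
      XtXinv_d <- diag(chol2inv(qr.R(qx)))
      se <- sqrt(outer(sigma2, pmax(XtXinv_d, 0)))
      pv <- stats::pf((coefs / se)^2, 1, df, lower.tail = FALSE)
      alpha[] <- coefs[, seq_len(k)]
      alpha_se[] <- se[, seq_len(k)]
      alpha_p[] <- pv[, seq_len(k)]
      beta[] <- coefs[, k + 1L]
      beta_se[] <- se[, k + 1L]
      n_used[] <- nrow(meta)
      complete <- TRUE
    } else {
      complete <- FALSE  # rank-deficient: fall through to per-ion fits
    }
  }
  if (!complete) {
    for (i in seq_len(nion)) {
      f <- tryCatch(fit_ion(mat[i, ], meta), error = function(e) NULL)
      if (is.null(f)) next  # all-missing ion: skipped
      alpha[i, names(f$alpha)] <- f$alpha
      alpha_se[i, names(f$alpha_se)] <- f$alpha_se
      alpha_p[i, names(f$alpha_p)] <- f$alpha_p
      beta[i] <- f$beta
      beta_se[i] <- f$beta_se
      n_used[i] <- f$n_used
    }
  }

  reliable <- !is.na(alpha) & !is.na(alpha_p) & alpha > 0 & alpha_p <= p_threshold
  cv <- ifelse(!is.na(alpha) & alpha > 0, alpha_se / alpha, NA_real_)
  structure(list(
    alpha = alpha, alpha_se = alpha_se, alpha_p = alpha_p,
    beta = beta, beta_se = beta_se, cv = cv, reliable = reliable,
    excluded = rowSums(reliable, na.rm = TRUE) == 0,
    n_used = n_used, p_threshold = p_threshold,
    cell_lines = ulines
  ), class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("steady_state_fit: %d ions x %d cell lines\n",
              nrow(x$alpha), length(x$cell_lines)))
  cat(sprintf("  reliable (alpha > 0, p <= %g) in >= 1 line: %d ions\n",
              x$p_threshold, sum(!x$excluded)))
  cat(sprintf("  excluded (background / below detection): %d ions\n",
              sum(x$excluded)))
  invisible(x)
}

#' Tidy per-(ion, cell line) coefficient table
#'
#' @param x A \code{steady_state_fit}.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return data.frame with one row per (ion, cell_line).
#' @export
as.data.frame.steady_state_fit <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  ions <- rownames(x$alpha)
  lines <- x$cell_lines
  out <- data.frame(
    ion = rep(ions, times = length(lines)),
    cell_line = rep(lines, each = length(ions)),
    alpha = as.vector(x$alpha),
    alpha_se = as.vector(x$alpha_se),
    alpha_p = as.vector(x$alpha_p),
    cv = as.vector(x$cv),
    reliable = as.vector(x$reliable),
    beta = rep(unname(x$beta), times = length(lines)),
    beta_se = rep(unname(x$beta_se), times = length(lines)),
    stringsAsFactors = FALSE
  )
  out[order(out$ion, out$cell_line), ]
}

#' Median coefficient of variation of reliable abundance estimates
#'
#' CV of an (ion, line) pair is the regression standard error of alpha divided
#' by the alpha estimate; the summary is the median over all reliable pairs,
#' reported as a percentage.
#'
#' @param fit A \code{steady_state_fit}.
#' @return Median CV in percent.
#' @export
summarize_cv <- function(fit) {
  cvs <- fit$cv[fit$reliable]
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0L) stop("no reliable (ion, cell line) pairs")
  100 * stats::median(cvs)
}

#' Per-sample abundance estimates
#'
#' Inverts the intensity model: abundance = (I - beta) / N_c, in intensity per
#' cell. Negative values are retained (measurement noise around the
#' background) so downstream statistics remain unbiased. Samples with zero
#' cell number are skipped (NA).
#'
#' @param mat Intensity matrix (ions x samples).
#' @param meta Sample metadata aligned with columns of \code{mat}.
#' @param fit A \code{steady_state_fit} for the same ions.
#' @return Matrix of abundances, ions x samples.
#' @export
per_sample_abundance <- function(mat, meta, fit) {
  meta <- as.data.frame(meta)
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  N <- meta$cell_number
  ab <- sweep(mat, 1, fit$beta[rownames(mat)], `-`)
  ab <- sweep(ab, 2, N, `/`)
  ab[, !is.na(N) & N == 0] <- NA_real_
  ab
}

#' One-way ANOVA of per-cell abundances across cell lines
#'
#' Tests, per ion, whether mean per-cell abundance differs across cell lines,
#' with Benjamini-Hochberg adjustment across ions.
#'
#' @param abundance Matrix of per-sample abundances (ions x samples), e.g.
#'   from \code{\link{per_sample_abundance}}.
#' @param cell_line Character vector of cell-line labels per sample.
#' @param q_threshold Significance cutoff on adjusted p-values (default 0.05).
#' @return data.frame with \code{ion}, \code{F}, \code{p}, \code{q},
#'   \code{significant}; ions with fewer than two lines of >= 2 samples are
#'   skipped (NA statistics).
#' @export
anova_across_lines <- function(abundance, cell_line, q_threshold = 0.05) {
  stopifnot(ncol(abundance) == length(cell_line))
  ions <- rownames(abundance)
  if (is.null(ions)) ions <- paste0("ion", seq_len(nrow(abundance)))
  Fv <- pv <- rep(NA_real_, nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    y <- abundance[i, ]
    ok <- !is.na(y)
    g <- factor(cell_line[ok])
    if (length(unique(g)) < 2L || sum(table(g) >= 2L) < 2L) next
    a <- stats::anova(stats::lm(y[ok] ~ g))
    Fv[i] <- a$`F value`[1]
    pv[i] <- a$`Pr(>F)`[1]
  }
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- stats::p.adjust(pv[!is.na(pv)], method = "BH")
  data.frame(ion = ions, F = Fv, p = pv, q = qv,
             significant = !is.na(qv) & qv <= q_threshold,
             stringsAsFactors = FALSE)
}
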