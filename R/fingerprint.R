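# Drug fingerprints: per-ion summaries of fold-change time courses across
# cell lines (conserved and cell-line-specific responses) and hypergeometric
# metabolite-set enrichment.

#' Summarize fold-change time courses across cell lines
#'
#' For each ion and cell line the time point with maximal absolute log2
#' fold-change is located and its signed value retained; the per-line minimal
#' p-value over the time course is retained as well. Ions are then summarized
#' across lines by the median of the signed maximal fold-changes, the product
#' of the per-line minimal p-values (a ranking score, not a calibrated
#' p-value) and the sample standard deviation of the per-line maxima (the
#' response-variability measure).
#'
#' @param fc Fold-change table from \code{\link{compute_fold_changes}}.
#' @param treatment Treatment label to summarize.
#' @param absolute If TRUE, summarize absolute rather than signed maximal
#'   fold-changes (default FALSE: signed values, matching the volcano-plot
#'   display).
#' @return data.frame per ion: \code{median_max_fc}, \code{combined_p},
#'   \code{sd_max_fc}, \code{n_lines}, plus per-line columns packed in the
#'   attribute \code{"per_line"}.
#' @export
summarize_across_lines <- function(fc, treatment, absolute = FALSE) {
  stopifnot(is.data.frame(fc), "log2fc" %in% names(fc))
  fc <- fc[fc$treatment == treatment & !is.na(fc$log2fc), , drop = FALSE]
  if (nrow(fc) == 0L) stop(sprintf("no fold-changes for treatment '%s'", treatment))
  key <- paste(fc$ion, fc$cell_line, sep = "\r")
  # per (ion, line): signed fc at the time of maximal |fc|; minimal p
  ord <- order(key, -abs(fc$log2fc))
  first <- !duplicated(key[ord])
  per_line <- fc[ord, ][first, c("ion", "cell_line", "log2fc"), drop = FALSE]
  names(per_line)[3] <- "max_fc"
  if (absolute) per_line$max_fc <- abs(per_line$max_fc)
  minp <- tapply(fc$pvalue, key, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) NA_real_ else min(p)
  })
  per_line$min_p <- as.numeric(minp[paste(per_line$ion, per_line$cell_line,
                                          sep = "\r")])

  split_idx <- split(seq_len(nrow(per_line)), per_line$ion)
  out <- data.frame(
    ion = names(split_idx),
    median_max_fc = vapply(split_idx, function(i)
      stats::median(per_line$max_fc[i]), numeric(1)),
    combined_p = vapply(split_idx, function(i) {
      p <- per_line$min_p[i]
      if (all(is.na(p))) NA_real_ else prod(p, na.rm = TRUE)
    }, numeric(1)),
    sd_max_fc = vapply(split_idx, function(i) {
      if (length(i) < 2L) NA_real_ else stats::sd(per_line$max_fc[i])
    }, numeric(1)),
    n_lines = vapply(split_idx, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "per_line") <- per_line
  out
}

#' Select ions with a conserved drug response
#'
#' An ion is selected when the absolute median maximal log2 fold-change is at
#' least \code{fc_cut} and the combined p-value (product of per-line minima)
#' is at most \code{p_cut}. Both bounds are inclusive.
#'
#' @param table Summary table from \code{\link{summarize_across_lines}}.
#' @param fc_cut Fold-change cutoff in log2 units (default 1).
#' @param p_cut Combined p-value cutoff (default 1e-10).
#' @return Character vector of selected ion ids.
#' @export
select_conserved <- function(table, fc_cut = 1.0, p_cut = 1e-10) {
  stopifnot(nrow(table) > 0L)
  sel <- !is.na(table$median_max_fc) & !is.na(table$combined_p) &
    abs(table$median_max_fc) >= fc_cut & table$combined_p <= p_cut
  table$ion[sel]
}

#' Select ions with a variable (cell-line-specific) response
#'
#' An ion is selected when the sample standard deviation (n-1 denominator) of
#' its per-line maximal fold-changes is at least \code{sd_cut} (inclusive).
#' Ions observed in a single line carry no variability information and are
#' skipped.
#'
#' @param table Summary table from \code{\link{summarize_across_lines}}.
#' @param sd_cut Standard-deviation cutoff in log2 units (default 1.5).
#' @return Character vector of selected ion ids.
#' @export
select_variable <- function(table, sd_cut = 1.5) {
  sel <- !is.na(table$sd_max_fc) & table$n_lines >= 2L & table$sd_max_fc >= sd_cut
  table$ion[sel]
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (default) or Storey's q-values with pi0
#' estimated by lambda-smoothing (natural smoothing spline over a lambda grid,
#' evaluated at the largest lambda). Storey estimation needs a reasonable
#' number of tests; below 100 it falls back to BH with a warning.
#'
#' @param ps Numeric vector of p-values in (0, 1].
#' @param method \code{"BH"} or \code{"storey"}.
#' @return Adjusted q-values, same length and order as \code{ps}.
#' @export
adjust_pvalues <- function(ps, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(ps) == 0L) return(numeric(0))
  stopifnot(all(is.na(ps) | (ps > 0 & ps <= 1)))
  if (method == "BH") return(stats::p.adjust(ps, method = "BH"))
  ok <- !is.na(ps)
  if (sum(ok) < 100L) {
    warning("fewer than 100 tests: pi0 not estimable, falling back to BH")
    return(stats::p.adjust(ps, method = "BH"))
  }
  p <- ps[ok]
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- min(max(stats::predict(fit, x = max(lambda))$y, 0), 1)
  if (pi0 <= 0) pi0 <- 1  # degenerate estimate: be conservative
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))[order(o)]
  res <- rep(NA_real_, length(ps))
  res[ok] <- q
  res
}

#' Hypergeometric pathway enrichment
#'
#' Tests each pathway for over-representation of selected ions among the
#' universe with the upper-tail hypergeometric test
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}, where N is the
#' universe size, K the pathway size within the universe, n the number of
#' selected ions and k the overlap. Pathway membership is evaluated on
#' metabolite ids; supply the ion-to-metabolite map via annotated ids.
#'
#' @param selected Character vector of selected ids (subset of universe).
#' @param universe Character vector of all tested ids.
#' @param pathways Named list of character vectors (pathway id -> member ids),
#'   e.g. from \code{\link{read_pathway_gmt}}.
#' @param q_cut Significance cutoff on adjusted values (default 0.001).
#' @param method Multiple-testing method for \code{\link{adjust_pvalues}}.
#' @return data.frame \code{pathway}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p}, \code{q}, \code{significant}, sorted by q then p. Pathways with
#'   no member in the universe are skipped.
#' @export
enrich_pathways <- function(selected, universe, pathways, q_cut = 0.001,
                            method = c("BH", "storey")) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe)) stop("selected ids must be a subset of the universe")
  if (is.data.frame(pathways)) stop("pathways must be a named list of member id vectors")
  members <- lapply(pathways, function(m) intersect(unique(m), universe))
  K <- vapply(members, length, integer(1))
  keep <- K > 0L
  members <- members[keep]; K <- K[keep]
  if (length(members) == 0L) {
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  N <- length(universe)
  n <- length(selected)
  k <- vapply(members, function(m) length(intersect(m, selected)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- adjust_pvalues(p, method = method)
  out <- data.frame(pathway = names(members), k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q <= q_cut,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}
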