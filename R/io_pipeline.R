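# Readers/writers for the TSV/GMT dialects and the end-to-end pipeline
# driver: annotate -> fit-steady-state -> fold-changes -> fingerprint ->
# enrichment.

.pkg_version <- function() {
  as.character(utils::packageVersion("metadyn"))
}

#' Write a TSV with an audit-trail header comment
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Named list of parameter values recorded in the header.
#' @param sep Field separator (default tab).
#' @export
write_table_audited <- function(df, path, params = list(), sep = "\t") {
  hdr <- sprintf("# metadyn %s%s", .pkg_version(),
                 if (length(params))
                   paste0(" | ", paste(names(params), unlist(params),
                                       sep = "=", collapse = " ")) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expected columns: \code{sample_id}, \code{cell_line}, \code{replicate},
#' \code{time_h}, \code{treatment}, \code{cell_number}, \code{confluence}.
#'
#' @param path TSV (or CSV with \code{sep = ","}) path; comment lines starting
#'   with '#' are ignored.
#' @param sep Field separator.
#' @return data.frame.
#' @export
read_sample_meta <- function(path, sep = "\t") {
  meta <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cell_line", "replicate", "time_h", "treatment",
            "cell_number", "confluence")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop(sprintf("metadata missing column '%s'", miss[1]))
  if (anyDuplicated(meta$sample_id)) {
    stop(sprintf("duplicated sample_id '%s'",
                 meta$sample_id[duplicated(meta$sample_id)][1]))
  }
  meta
}

#' Read an intensity matrix
#'
#' First column is the ion id (or m/z), remaining columns are sample ids
#' matching the metadata. Empty cells become missing values (never zero).
#'
#' @param path TSV/CSV path.
#' @param meta Optional metadata: every sample column must appear in it.
#' @param sep Field separator.
#' @return Numeric matrix, ions x samples, rownames = ion ids.
#' @export
read_intensity_matrix <- function(path, meta = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("intensity matrix needs an ion column plus sample columns")
  if (anyDuplicated(names(df)[-1])) {
    stop(sprintf("duplicated sample column '%s'",
                 names(df)[-1][duplicated(names(df)[-1])][1]))
  }
  ions <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad)) {
        stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(vals)[j]))
      }
      vals[[j]] <- suppress
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ions
  if (!is.null(meta)) {
    miss <- setdiff(colnames(mat), meta$sample_id)
    if (length(miss)) stop(sprintf("sample column '%s' absent from metadata", miss[1]))
  }
  mat
}

#' Read a metabolite reference table
#'
#' TSV with header \code{id name formula is_keto_acid source}; computes
#' neutral monoisotopic masses.
#'
#' @param path TSV path.
#' @param sep Field separator.
#' @return Metabolite table (see \code{\link{metabolite_table}}).
#' @export
read_metabolite_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  metabolite_table(df)
}

#' Read pathway sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields: id, description,
#' then member ids. Duplicate members are deduplicated with a warning.
#'
#' @param path GMT path.
#' @return Named list of member-id character vectors, with descriptions in
#'   attribute \code{"description"}.
#' @export
read_pathway_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), description = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has %d field(s); need id, description, members",
                 which(nf < 3L)[1], nf[which(nf < 3L)[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  members <- lapply(parts, function(x) {
    m <- x[-(1:2)]
    m <- m[nzchar(m)]
    if (anyDuplicated(m)) {
      warning(sprintf("duplicated member(s) in pathway '%s'; deduplicated", x[1]))
      m <- unique(m)
    }
    m
  })
  names(members) <- ids
  attr(members, "description") <- stats::setNames(desc, ids)
  members
}

#' Write pathway sets in GMT format
#'
#' @param pathways Named list of member-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default "na").
#' @export
write_pathway_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(pathways)), names(pathways))
  }
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, descriptions[[id]], pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' JSON file holding paths (\code{matrix}, \code{meta}, \code{metabolites},
#' \code{gmt}), thresholds and options; missing thresholds take the published
#' defaults.
#'
#' @param path JSON path.
#' @return Named list merged over the defaults of
#'   \code{\link{pipeline_defaults}}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- pipeline_defaults()
  def[names(cfg)] <- cfg
  def
}

#' Default pipeline thresholds
#'
#' The published analysis thresholds: 0.003 amu annotation tolerance, 80\%
#' confluence exclusion, reliability p <= 0.001, conserved-fingerprint cuts
#' |log2 FC| >= 1 and combined p <= 1e-10, variability cut SD >= 1.5, and
#' enrichment q <= 0.001.
#'
#' @return Named list of thresholds and options.
#' @export
pipeline_defaults <- function() {
  list(tolerance = 0.003, max_confluence = 0.80, p_reliable = 0.001,
       fc_cut = 1.0, p_cut = 1e-10, sd_cut = 1.5, q_cut = 0.001,
       correction = "BH", treatment = NULL, seed = 1L)
}

#' Run the full profiling pipeline
#'
#' Executes annotation, steady-state model fitting, dynamic fold-change
#' computation, fingerprint extraction and pathway enrichment in order, and
#' (optionally) writes each stage's table plus a machine-readable run summary.
#' Deterministic for fixed inputs: rerunning with the same inputs produces
#' identical outputs.
#'
#' @param ion_mzs Measured ion m/z vector (names used as ion ids if present;
#'   otherwise the formatted m/z is the id).
#' @param metabolites Metabolite table.
#' @param steady_mat,steady_meta Unperturbed intensity matrix and metadata.
#' @param treated_mat,treated_meta Treated intensity matrix and metadata.
#' @param pathways Named list of pathway member metabolite ids (optional; skip
#'   enrichment when NULL).
#' @param config Thresholds/options list (see \code{\link{pipeline_defaults}});
#'   \code{treatment} defaults to the first non-"none" label in the treated
#'   metadata.
#' @param out_dir Output directory for stage TSVs and the run log (optional).
#' @return List with \code{annotations}, \code{fit}, \code{fold_changes},
#'   \code{fingerprint}, \code{conserved}, \code{variable}, \code{enrichment}
#'   and \code{config}.
#' @export
run_pipeline <- function(ion_mzs, metabolites, steady_mat, steady_meta,
                         treated_mat, treated_meta, pathways = NULL,
                         config = pipeline_defaults(), out_dir = NULL) {
  def <- pipeline_defaults()
  def[names(config)] <- config
  config <- def
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. annotation: map measured ions to metabolites
  lib <- stage("annotate", build_ion_library(metabolites))
  ann <- stage("annotate", annotate_ions(ion_mzs, lib, config$tolerance))
  ion_ids <- names(ion_mzs)
  if (is.null(ion_ids)) ion_ids <- sprintf("%.6f", ion_mzs)
  ann$ion <- ion_ids[match(ann$ion_mz, ion_mzs)]

  # restrict matrices to annotated ions
  keep <- intersect(rownames(steady_mat), ann$ion)
  if (length(keep) == 0L) stop("[annotate] no annotated ion present in the matrix")
  smat <- steady_mat[keep, , drop = FALSE]

  # 2. steady-state model
  fit <- stage("fit-steady-state",
               fit_all(smat, steady_meta, p_threshold = config$p_reliable,
                       max_confluence = config$max_confluence))

  # 3. dynamic fold-changes
  tmat <- treated_mat[intersect(rownames(treated_mat), keep), , drop = FALSE]
  fc <- stage("fold-changes", compute_fold_changes(tmat, treated_meta, fit))

  # 4. fingerprint
  treatment <- config$treatment
  if (is.null(treatment)) {
    treatment <- setdiff(unique(fc$treatment), "none")[1]
  }
  fp <- stage("fingerprint", summarize_across_lines(fc, treatment))
  conserved <- select_conserved(fp, config$fc_cut, config$p_cut)
  variable <- select_variable(fp, config$sd_cut)
  fp$selected_conserved <- fp$ion %in% conserved
  fp$selected_variable <- fp$ion %in% variable

  # 5. enrichment on best-match metabolite ids over the reliable universe
  enrichment <- NULL
  if (!is.null(pathways)) {
    ion2met <- stats::setNames(ann$metabolite_id, ann$ion)
    universe_ions <- rownames(fit$alpha)[!fit$excluded]
    universe <- unique(ion2met[universe_ions])
    selected <- unique(ion2met[conserved])
    enrichment <- stage("enrich",
                        enrich_pathways(selected, universe, pathways,
                                        q_cut = config$q_cut,
                                        method = config$correction))
  }

  res <- list(annotations = ann, fit = fit, fold_changes = fc,
              fingerprint = fp, conserved = conserved, variable = variable,
              enrichment = enrichment, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pl <- config[c("tolerance", "max_confluence", "p_reliable", "fc_cut",
                   "p_cut", "sd_cut", "q_cut", "correction")]
    write_table_audited(ann, file.path(out_dir, "annotations.tsv"), pl)
    write_table_audited(as.data.frame(fit), file.path(out_dir, "steady_state_fit.tsv"), pl)
    write_table_audited(fc, file.path(out_dir, "fold_changes.tsv"), pl)
    write_table_audited(fp, file.path(out_dir, "fingerprint.tsv"), pl)
    if (!is.null(enrichment)) {
      write_table_audited(enrichment, file.path(out_dir, "enrichment.tsv"), pl)
    }
    summary <- list(version = .pkg_version(), thresholds = pl,
                    n_ions_annotated = nrow(ann),
                    n_ions_reliable = sum(!fit$excluded),
                    median_cv_percent = tryCatch(summarize_cv(fit),
                                                 error = function(e) NA),
                    treatment = treatment,
                    n_conserved = length(conserved),
                    n_variable = length(variable))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
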