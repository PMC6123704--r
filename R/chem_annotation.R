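# Sum-formula arithmetic, monoisotopic masses and accurate-mass ion annotation.

#' Monoisotopic masses of the most abundant isotope (Da)
#'
#' Masses of the most abundant naturally occurring isotope of each supported
#' element, in dalton, taken from the NIST Atomic Weights and Isotopic
#' Compositions compilation (>= 8 decimals where available).
#'
#' @format Named numeric vector, names are element symbols.
#' @export
element_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213,
  Fe = 55.9349375,
  Mg = 23.9850417,
  Ca = 39.96259098,
  Zn = 63.9291422
)

#' Mass of a proton in dalton
#'
#' Mass of the hydrogen atom minus the electron mass; subtracted from the
#' neutral monoisotopic mass to obtain the m/z of the deprotonated [M-H]- ion
#' observed in negative-mode electrospray.
#'
#' @export
proton_mass <- 1.007276467

# net formula change of phenylhydrazone formation: + C6H8N2 - H2O
.phenylhydrazone_delta <- c(C = 6L, H = 6L, N = 2L, O = -1L)

#' Parse a molecular sum formula
#'
#' Parses a flat sum formula such as \code{"C9H17NO5"} into named element
#' counts. The grammar is element symbol (capital letter plus optional lower
#' case letter) followed by an optional positive integer count; repeated
#' mentions of an element are summed. Parentheses, charges, isotope labels and
#' hydrate dots are not supported: library exports must be pre-expanded.
#'
#' @param text Formula string. An empty string yields the empty formula.
#' @return Named integer vector of element counts (a "sum formula"), in
#'   canonical Hill order (C, H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C9H17NO5")   # pantothenate
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    if (!grepl("^[A-Z]", substr(text, pos, pos))) {
      stop(sprintf("malformed formula '%s' at position %d", text, pos))
    }
    # prefer the two-letter symbol when it is a known element, else one letter
    sym <- substr(text, pos, min(pos + 1L, n))
    if (!(nchar(sym) == 2L && grepl("^[A-Z][a-z]$", sym) &&
          sym %in% names(element_masses))) {
      sym <- substr(text, pos, pos)
      if (!sym %in% names(element_masses)) {
        two <- substr(text, pos, min(pos + 1L, n))
        bad <- if (grepl("^[A-Z][a-z]$", two)) two else sym
        stop(sprintf("unknown element symbol '%s' in formula '%s'", bad, text))
      }
    }
    rest <- substr(text, pos + nchar(sym), n)
    digits <- regmatches(rest, regexpr("^[0-9]+", rest))
    cnt <- if (length(digits) == 0L) 1L else as.integer(digits)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(sym) + if (length(digits)) nchar(digits) else 0L
  }
  canonical_formula(counts)
}

#' Put a sum formula in canonical Hill order
#'
#' @param f Named integer vector of element counts.
#' @return The same counts ordered C, H, then alphabetically; zero counts
#'   dropped.
#' @export
canonical_formula <- function(f) {
  f <- f[f != 0]
  if (length(f) == 0L) return(stats::setNames(integer(0), character(0)))
  if (any(f < 0)) stop("negative element count in formula")
  bad <- setdiff(names(f), names(element_masses))
  if (length(bad)) stop(sprintf("unknown element symbol '%s'", bad[1]))
  syms <- names(f)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  storage.mode(f) <- "integer"
  f[ord]
}

#' Render a sum formula as a Hill-order string
#'
#' @param f Named integer vector of element counts (or formula string).
#' @return Canonical string, e.g. \code{"C9H17NO5"}; counts of 1 are implicit.
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", as.character(f)), collapse = "")
}

# accept either a formula string or a named count vector
as_formula <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  canonical_formula(f)
}

#' Monoisotopic mass of a sum formula
#'
#' Sum over elements of count times the mass of the most abundant isotope
#' (\code{\link{element_masses}}).
#'
#' @param f Sum formula: named integer vector or formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C3H9NO3S")   # 139.030314, the HOT lock-mass compound
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0.0)
  sum(element_masses[names(f)] * as.numeric(f))
}

#' m/z of the deprotonated [M-H]- ion
#'
#' Negative-mode electrospray ionization is modelled as deprotonation only:
#' the observed m/z is the neutral monoisotopic mass minus the proton mass
#' (H atom minus the electron, \code{\link{proton_mass}}).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @return m/z in Da.
#' @examples
#' deprotonated_mz(monoisotopic_mass("C3H9NO3S"))  # 138.0230374
#' @export
deprotonated_mz <- function(neutral_mass) {
  mz <- neutral_mass - proton_mass
  if (any(mz <= 0)) stop("deprotonated m/z must be positive; neutral mass too small")
  mz
}

#' Phenylhydrazone derivative of an alpha-keto acid formula
#'
#' Phenylhydrazine in the extraction solvent converts alpha-keto acids to
#' their phenylhydrazones; the net sum-formula change is +C6H8N2 -H2O.
#'
#' @param f Sum formula of the underivatized metabolite (vector or string);
#'   must contain at least 2 H and 1 O.
#' @return Derivatized sum formula.
#' @examples
#' phenylhydrazone_formula("C3H4O3")  # pyruvate -> C9H10N2O2
#' @export
phenylhydrazone_formula <- function(f) {
  f <- as_formula(f)
  h <- if ("H" %in% names(f)) f[["H"]] else 0L
  o <- if ("O" %in% names(f)) f[["O"]] else 0L
  if (h < 2L || o < 1L) {
    stop("phenylhydrazone derivatization requires at least H2 and O1 in the formula")
  }
  for (el in names(.phenylhydrazone_delta)) {
    cur <- if (el %in% names(f)) f[[el]] else 0L
    f[el] <- cur + .phenylhydrazone_delta[[el]]
  }
  canonical_formula(f)
}

#' Assemble a metabolite reference table
#'
#' Validates a metabolite table (id, name, formula, is_keto_acid, source) and
#' computes the neutral monoisotopic mass of each entry.
#'
#' @param df data.frame with columns \code{id}, \code{name}, \code{formula};
#'   optional \code{is_keto_acid} (logical, default FALSE) and \code{source}.
#' @return data.frame with an added \code{neutral_mass} column.
#' @export
metabolite_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "name", "formula") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop(sprintf("duplicate metabolite id '%s'", df$id[duplicated(df$id)][1]))
  }
  if (is.null(df$is_keto_acid)) df$is_keto_acid <- FALSE
  if (is.null(df$source)) df$source <- "user"
  df$is_keto_acid <- as.logical(df$is_keto_acid)
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  rownames(df) <- NULL
  df
}

#' Build the expected-ion library
#'
#' One deprotonated [M-H]- entry per metabolite, plus one additional entry for
#' the deprotonated phenylhydrazone of every metabolite flagged as an
#' alpha-keto acid. Entries are sorted by expected m/z.
#'
#' @param metabolites Metabolite table as returned by
#'   \code{\link{metabolite_table}} (or a raw data.frame thereof).
#' @return data.frame with columns \code{metabolite_id}, \code{expected_mz},
#'   \code{derivatized}.
#' @export
build_ion_library <- function(metabolites) {
  if (!"neutral_mass" %in% names(metabolites)) {
    metabolites <- metabolite_table(metabolites)
  }
  if (anyDuplicated(metabolites$id)) {
    stop(sprintf("duplicate metabolite id '%s'",
                 metabolites$id[duplicated(metabolites$id)][1]))
  }
  lib <- data.frame(
    metabolite_id = metabolites$id,
    expected_mz = deprotonated_mz(metabolites$neutral_mass),
    derivatized = FALSE,
    stringsAsFactors = FALSE
  )
  keto <- metabolites[isTRUE_vec(metabolites$is_keto_acid), , drop = FALSE]
  if (nrow(keto) > 0L) {
    dmass <- vapply(keto$formula, function(ff) {
      monoisotopic_mass(phenylhydrazone_formula(ff))
    }, numeric(1))
    lib <- rbind(lib, data.frame(
      metabolite_id = keto$id,
      expected_mz = deprotonated_mz(dmass),
      derivatized = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  lib <- lib[order(lib$expected_mz, lib$metabolite_id), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Annotate measured ions against the expected-ion library
#'
#' Matches each measured ion m/z against the library within an absolute mass
#' tolerance (inclusive). Each ion is reported with its best match (smallest
#' absolute mass error; ties broken by lexicographically smallest metabolite
#' id) and the full list of matches within tolerance. Ions with no match are
#' omitted. Implemented by binary search on the sorted library,
#' O((n + m) log m).
#'
#' @param ion_mzs Numeric vector of measured ion m/z values.
#' @param library Ion library from \code{\link{build_ion_library}}.
#' @param tolerance Absolute tolerance in Da (default 0.003 amu).
#' @return data.frame with one row per annotated ion: \code{ion_mz},
#'   \code{metabolite_id} (best match), \code{expected_mz},
#'   \code{mass_error_da} (signed, measured minus expected),
#'   \code{derivatized}, \code{n_matches} and \code{all_matches}
#'   (semicolon-separated \code{id:error} pairs).
#' @export
annotate_ions <- function(ion_mzs, library, tolerance = 0.003) {
  if (is.null(library) || nrow(library) == 0L) stop("empty ion library")
  stopifnot(tolerance > 0)
  lib <- library[order(library$expected_mz), , drop = FALSE]
  mzs <- lib$expected_mz
  lo <- findInterval(ion_mzs - tolerance, mzs) + 1L   # first index >= mz - tol
  hi <- findInterval(ion_mzs + tolerance, mzs)        # last index  <= mz + tol
  out <- vector("list", length(ion_mzs))
  for (k in seq_along(ion_mzs)) {
    if (lo[k] > hi[k]) next
    idx <- lo[k]:hi[k]
    err <- ion_mzs[k] - mzs[idx]
    keep <- abs(err) <= tolerance
    idx <- idx[keep]; err <- err[keep]
    if (length(idx) == 0L) next
    ord <- order(abs(err), lib$metabolite_id[idx])
    idx <- idx[ord]; err <- err[ord]
    out[[k]] <- data.frame(
      ion_mz = ion_mzs[k],
      metabolite_id = lib$metabolite_id[idx[1]],
      expected_mz = mzs[idx[1]],
      mass_error_da = err[1],
      derivatized = lib$derivatized[idx[1]],
      n_matches = length(idx),
      all_matches = paste(sprintf("%s:%.6f", lib$metabolite_id[idx], err),
                          collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(ion_mz = numeric(0), metabolite_id = character(0),
                      expected_mz = numeric(0), mass_error_da = numeric(0),
                      derivatized = logical(0), n_matches = integer(0),
                      all_matches = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
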