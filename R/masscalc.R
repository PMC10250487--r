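# Monoisotopic masses of the most abundant isotope (CODATA/IUPAC).
ATOMIC_MASSES <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)

H_MASS <- ATOMIC_MASSES[["H"]]

#' Parse a molecular formula
#'
#' Parses Hill-style formulas such as `"C22H32O2"` or `"C45H78NO8P"` into a
#' named element-count vector. Element symbols are one upper-case letter
#' optionally followed by a lower-case letter; a missing count means 1.
#'
#' @param text formula string.
#' @param masses named vector of atomic masses defining the known elements
#'   (extensible; defaults to C, H, N, O, P, S).
#' @return named integer vector of element counts.
#' @seealso [formulaToText()] for the canonical round-trip.
#' @examples
#' parseFormula("C22H32O2")
#' @export
parseFormula <- function(text, masses = ATOMIC_MASSES) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[ _]", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: '", text, "'")
  counts <- integer(0)
  for (tk in toks) {
    sym <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(masses))
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    if (n < 1L) stop("element counts must be positive in '", text, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Canonical text of a parsed formula (Hill order)
#'
#' @param f named element-count vector as returned by [parseFormula()].
#' @return character formula, C then H then the rest alphabetically.
#' @export
formulaToText <- function(f) {
  syms <- names(f)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  paste0(vapply(ord, function(s)
    paste0(s, if (f[[s]] > 1L) f[[s]] else ""), ""), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of most-abundant-isotope atomic masses (carbon-12 is exactly 12 Da).
#'
#' @inheritParams formulaToText
#' @param masses named atomic-mass vector.
#' @return mass in Da.
#' @export
monoisotopicMass <- function(f, masses = ATOMIC_MASSES) {
  if (is.character(f)) f <- parseFormula(f, masses)
  bad <- setdiff(names(f), names(masses))
  if (length(bad)) stop("no mass for element(s): ", paste(bad, collapse = ", "))
  sum(masses[names(f)] * f)
}

#' Deprotonated-ion ([M-H]-) accurate mass
#'
#' Neutral monoisotopic mass minus one hydrogen-atom mass, the convention
#' used for negative-mode fingerprint annotation (no electron-mass term).
#'
#' @inheritParams monoisotopicMass
#' @return ion mass in Da.
#' @examples
#' mhIonMass("C18H30O2")  # alpha-linolenic acid, 277.2168
#' @export
mhIonMass <- function(f, masses = ATOMIC_MASSES) {
  if (is.character(f)) f <- parseFormula(f, masses)
  if (!"H" %in% names(f) || f[["H"]] < 1L)
    stop("cannot deprotonate a hydrogen-free formula")
  monoisotopicMass(f, masses) - H_MASS
}

#' The curated salmon lipid marker panel
#'
#' Eighteen lipid markers (unsaturated and branched fatty acids, primary
#' amides, N-acyl amines, PG/PC phospholipids and a triacylglycerol) that
#' separate the five salmon origin/production groups, with the published
#' 0.2-Da ion-bin label, molecular formula and accurate deprotonated-ion
#' mass. Two consistency flags are computed at load time:
#' `discrepant` marks records whose published mass differs from the
#' computed \eqn{[M-H]^-} mass by more than 5e-4 Da (four records; the
#' published value stays authoritative for annotation, the computed one for
#' validation), and `bin_discrepant` marks records whose published bin
#' label is not the 0.2-Da bin that actually contains the published mass
#' (three records).
#'
#' @param file optional path to a CSV with columns
#'   `bin,formula,accurate_mass,lipid_id,lipid_class`.
#' @return data.frame with the shipped columns plus `computed_mass`,
#'   `mass_delta`, `discrepant`, `mass_bin`, `bin_discrepant`.
#' @export
markerPanel <- function(file = system.file("extdata", "salmon_marker_panel.csv",
                                           package = "fuseMS")) {
  p <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("bin", "formula", "accurate_mass", "lipid_id", "lipid_class")
  if (!all(need %in% names(p)))
    stop("marker panel must have columns: ", paste(need, collapse = ", "))
  p$computed_mass <- vapply(p$formula, mhIonMass, numeric(1))
  p$mass_delta <- p$computed_mass - p$accurate_mass
  p$discrepant <- abs(p$mass_delta) > 5e-4
  p$mass_bin <- binLabelOf(p$accurate_mass)
  p$bin_discrepant <- abs(p$mass_bin - p$bin) > 1e-9
  p
}

# 0.2-Da bin label containing an m/z value on the default 100-1200 axis
binLabelOf <- function(mz, lo = 100, width = 0.2) {
  round(lo + (floor((mz - lo) / width) + 0.5) * width, 1)
}

#' Annotate m/z bins against a marker panel
#'
#' Each marker is attached to the unique bin whose labelled interval
#' `[label - tolerance, label + tolerance)` contains the marker's published
#' accurate mass; bins matching no marker are unannotated.
#'
#' @param binLabels numeric vector of unique bin labels (bin centres).
#' @param panel marker panel data.frame (see [markerPanel()]).
#' @param tolerance half-width of the labelled interval in Da (default 0.1,
#'   i.e. 0.2-Da bins).
#' @return data.frame `bin`, `lipid_id`, `lipid_class`, `accurate_mass`,
#'   `computed_mass`, one row per annotated bin/marker pair.
#' @export
annotateBins <- function(binLabels, panel = markerPanel(), tolerance = 0.1) {
  if (anyDuplicated(binLabels)) stop("bin labels must be unique")
  out <- lapply(seq_len(nrow(panel)), function(i) {
    m <- panel$accurate_mass[i]
    hit <- which(binLabels - tolerance <= m + 1e-9 &
                 m < binLabels + tolerance - 1e-9)
    if (length(hit) > 1L)
      stop(sprintf("marker %s (%.4f Da) matches %d bins; tolerance too wide",
                   panel$lipid_id[i], m, length(hit)))
    if (length(hit) == 0L) return(NULL)
    data.frame(bin = binLabels[hit], lipid_id = panel$lipid_id[i],
               lipid_class = panel$lipid_class[i], accurate_mass = m,
               computed_mass = if ("computed_mass" %in% names(panel))
                 panel$computed_mass[i] else NA_real_)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bin = numeric(0), lipid_id = character(0),
                      lipid_class = character(0), accurate_mass = numeric(0),
                      computed_mass = numeric(0))
  out
}
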