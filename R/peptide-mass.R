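## Monoisotopic peptide masses and modification-state assignment.
##
## The arithmetic is deliberately minimal: residue monoisotopic masses
## (standard IUPAC values, 6 decimals so 4-decimal MH+ values round
## correctly) summed with one water, plus fixed deltas for the supported
## lysine modifications, plus one proton for the singly protonated species
## MH+. This is what is needed to tell apart near-isobaric modification
## states (acetyl vs trimethyl differ by only 0.03638 Da) from an accurate
## measured mass.

RESIDUE_MONO_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MOD_DELTA <- c(
  acetyl = 42.010565,
  methyl = 14.015650,
  dimethyl = 28.031300,
  trimethyl = 42.046950
)

WATER_MONO <- 18.010565
PROTON_MASS <- 1.007276

#' Monoisotopic MH+ of a (modified) peptide
#'
#' Sum of residue monoisotopic masses plus one water gives the neutral
#' peptide mass; modification deltas (acetyl +42.0106, methyl +14.0157,
#' dimethyl +28.0313, trimethyl +42.0470 Da) and one proton (+1.0073)
#' give the singly protonated species.
#'
#' @param sequence Peptide string over the 20 standard one-letter codes.
#' @param modifications `NULL`, or a data frame with columns `position`
#'   (1-based residue index) and `mod` (one of `"acetyl"`, `"methyl"`,
#'   `"dimethyl"`, `"trimethyl"`); at most one modification per position.
#' @return MH+ in Da.
#' @examples
#' monoisotopic_mh("RHRKVLR",
#'                 data.frame(position = 4, mod = "dimethyl")) # 992.6588
#' @export
monoisotopic_mh <- function(sequence, modifications = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- RESIDUE_MONO_MASS[aa]
  if (anyNA(m))
    stop("unknown residue(s): ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  mass <- sum(m) + WATER_MONO
  if (!is.null(modifications) && nrow(modifications) > 0) {
    pos <- as.integer(modifications$position)
    if (any(pos < 1 | pos > length(aa)))
      stop("modification position outside the sequence")
    if (anyDuplicated(pos))
      stop("at most one modification per position")
    d <- MOD_DELTA[as.character(modifications$mod)]
    if (anyNA(d))
      stop("unknown modification(s): ",
           paste(unique(modifications$mod[is.na(d)]), collapse = ", "))
    mass <- mass + sum(d)
  }
  mass + PROTON_MASS
}

#' Build a table of candidate modified species for one peptide
#'
#' @param sequence Peptide string.
#' @param position Residue index carrying the candidate modification.
#' @param mods Modification names to enumerate.
#' @return Data frame `name`, `sequence`, `position`, `mod`, `mh_plus`.
#' @export
peptide_candidates <- function(sequence, position,
                               mods = names(MOD_DELTA)) {
  mh <- vapply(mods, function(m)
    monoisotopic_mh(sequence, data.frame(position = position, mod = m)),
    numeric(1))
  data.frame(name = mods, sequence = sequence, position = position,
             mod = mods, mh_plus = unname(mh), stringsAsFactors = FALSE)
}

#' Assign a modification state from an accurate measured mass
#'
#' Picks the candidate whose theoretical MH+ is closest to the measured
#' m/z. The call is accepted only when that candidate is within
#' `tolerance` and no competing candidate could explain the measurement:
#' a second candidate that also lies within `tolerance`, or whose distance
#' is within `margin` of the best (e.g. a measurement midway between two
#' species), makes the call `"ambiguous"`. No candidate within tolerance
#' gives `"no_match"`.
#'
#' @param measured_mz Measured MH+ in Da.
#' @param candidates Data frame with columns `name` and `mh_plus` (see
#'   [peptide_candidates()]).
#' @param tolerance Acceptance window in Da.
#' @param margin Minimum separation in Da between the best and second-best
#'   absolute mass errors for an unambiguous call (default 0.005).
#' @return List with `status` (`"match"`, `"ambiguous"`, `"no_match"`),
#'   `best` (candidate name or `NA`), `delta` (measured - theoretical),
#'   `tolerance`.
#' @export
assign_modification <- function(measured_mz, candidates, tolerance,
                                margin = 0.005) {
  if (nrow(candidates) == 0) stop("no candidates supplied")
  if (tolerance <= 0) stop("tolerance must be positive")
  err <- abs(measured_mz - candidates$mh_plus)
  o <- order(err)
  best <- o[1]
  status <- "match"
  if (err[best] > tolerance) {
    status <- "no_match"
  } else if (nrow(candidates) > 1) {
    second <- o[2]
    if (err[second] <= tolerance || (err[second] - err[best]) < margin)
      status <- "ambiguous"
  }
  list(
    status = status,
    best = if (status == "match") candidates$name[best] else NA_character_,
    delta = if (status == "match")
      measured_mz - candidates$mh_plus[best] else NA_real_,
    tolerance = tolerance
  )
}
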