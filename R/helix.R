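#' Peptide sequence with numbering offset
#'
#' @param sequence one-letter amino-acid string (20 canonical residues).
#' @param name optional peptide name.
#' @param offset residue number of the first residue in the parent
#'   protein (default 1).
#' @return a \code{peptide} object.
#' @export
peptide <- function(sequence, name = NULL, offset = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stopf("'sequence' must be a non-empty string")
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% names(residue_classes))
  if (length(bad) > 0L)
    stopf("non-canonical residue '%s' at position %d",
          aa[bad[1L]], offset + bad[1L] - 1L)
  structure(list(sequence = sequence, residues = aa,
                 name = name %||% sequence,
                 offset = check_count(offset, "offset")),
            class = "peptide")
}

# Residue classes of the helical-wheel display convention used for
# membrane-targeting sequences: bulky/apolar side chains vs basic
# residues vs small hydrophilic residues. A partition of the 20
# canonical letters; alanine is classed hydrophobic (standard usage).
residue_classes <- c(
  F = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  V = "hydrophobic", M = "hydrophobic", W = "hydrophobic",
  Y = "hydrophobic", A = "hydrophobic",
  K = "basic", R = "basic", H = "basic",
  G = "small_hydrophilic", S = "small_hydrophilic",
  T = "small_hydrophilic", N = "small_hydrophilic",
  Q = "small_hydrophilic",
  C = "other", P = "other", D = "other", E = "other")

# Hydrophobicity scales (data tables, swappable). "eisenberg" is the
# Eisenberg consensus scale.
hydrophobicity_scales <- list(
  eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  kyte_doolittle = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2))

#' Helical-wheel residue classification
#'
#' Projects the peptide on an ideal alpha-helical wheel (100 degrees per
#' residue, 3.6 residues per turn) and classifies each residue as
#' hydrophobic (F L I V M W Y A), basic (K R H), small hydrophilic
#' (G S T N Q) or other (C P D E).
#'
#' @param p a \code{\link{peptide}} (or a plain sequence string).
#' @return data.frame: position (parent-protein numbering), residue,
#'   wheel_angle (degrees, modulo 360), class.
#' @export
classify_residues <- function(p) {
  if (is.character(p)) p <- peptide(p)
  if (!inherits(p, "peptide")) stopf("'p' must be a peptide")
  i <- seq_along(p$residues) - 1L
  data.frame(position = p$offset + i,
             residue = p$residues,
             wheel_angle = (i * 100) %% 360,
             class = unname(residue_classes[p$residues]))
}

#' Hydrophobic moment of a peptide
#'
#' Mean-vector amphipathicity on an ideal helical wheel:
#' \deqn{\mu_H = \left| \sum_i h_i (\cos(100^\circ i), \sin(100^\circ i)) \right| / n}
#' with \eqn{h_i} the per-residue hydrophobicity from the chosen scale.
#' Measures how strongly hydrophobic residues cluster on one helix face;
#' a homopolymer spanning whole turns scores exactly 0.
#'
#' @param p a \code{\link{peptide}} or sequence string.
#' @param scale scale name; see \code{names(tirfdyn:::hydrophobicity_scales)}.
#' @return per-residue hydrophobic moment (dimensionless, >= 0).
#' @export
hydrophobic_moment <- function(p, scale = "eisenberg") {
  if (is.character(p)) p <- peptide(p)
  if (!inherits(p, "peptide")) stopf("'p' must be a peptide")
  if (!scale %in% names(hydrophobicity_scales))
    stopf("unknown scale '%s'; available: %s", scale,
          paste(names(hydrophobicity_scales), collapse = ", "))
  h <- hydrophobicity_scales[[scale]][p$residues]
  ang <- (seq_along(h) - 1L) * 100 * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}
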