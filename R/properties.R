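#' Peptide net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: the N-terminus
#' and side chains of H, K, R contribute positive fractions
#' `1 / (1 + 10^(pH - pK))`; the C-terminus and side chains of C, D, E, Y
#' contribute negative fractions `1 / (1 + 10^(pK - pH))`. The pK set
#' ships as an editable table (EMBOSS-style values by default).
#'
#' @param peptides Character vector of peptide sequences.
#' @param pH pH at which to evaluate the charge (default 7.0).
#' @param pk Optional data frame with columns `group`, `pk`, `sign`
#'   overriding the shipped table.
#' @return Numeric vector of net charges (elementary charge units).
#' @export
net_charge <- function(peptides, pH = 7, pk = NULL) {
  pk <- pk %||% read_resource("pk_values.tsv")
  vapply(peptides, function(p) {
    chars <- aa_chars(p)
    total <- 0
    for (i in seq_len(nrow(pk))) {
      g <- pk$group[i]
      n <- if (g %in% c("Nterm", "Cterm")) 1L else sum(chars == g)
      if (n == 0L) next
      frac <- if (pk$sign[i] == "positive") {
        1 / (1 + 10^(pH - pk$pk[i]))
      } else {
        -1 / (1 + 10^(pk$pk[i] - pH))
      }
      total <- total + n * frac
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Isoelectric point
#'
#' Root of [net_charge()] over pH in [0, 14], found by bisection to a
#' tolerance of 1e-4 pH units. If the charge does not change sign on the
#' interval (no isoelectric pH), the nearer boundary is returned with a
#' warning.
#'
#' @inheritParams net_charge
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(peptides, pk = NULL) {
  pk <- pk %||% read_resource("pk_values.tsv")
  vapply(peptides, function(p) {
    f <- function(pH) net_charge(p, pH = pH, pk = pk)
    lo <- f(0); hi <- f(14)
    if (sign(lo) == sign(hi)) {
      warn(sprintf("No isoelectric point in [0, 14] for '%s'.", p))
      return(if (abs(lo) < abs(hi)) 0 else 14)
    }
    uniroot(f, c(0, 14), tol = 1e-4)$root
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of per-residue hydrophobicity values (Eisenberg
#' consensus scale by default, shipped as an editable table).
#'
#' @param peptides Character vector of peptide sequences.
#' @param scale Optional named numeric vector residue -> hydrophobicity.
#' @return Numeric vector of mean hydrophobicities.
#' @export
mean_hydrophobicity <- function(peptides, scale = NULL) {
  scale <- scale %||% hydrophobicity_values()
  vapply(peptides, function(p) {
    h <- scale[aa_chars(p)]
    if (any(is.na(h))) {
      abort(sprintf("Residue missing from hydrophobicity scale in '%s'.", p))
    }
    mean(h)
  }, numeric(1), USE.NAMES = FALSE)
}

hydrophobicity_values <- function() {
  tab <- read_resource("hydrophobicity_eisenberg.tsv")
  setNames(tab$hydrophobicity, tab$residue)
}

#' Hydrophobic moment (helical amphipathicity)
#'
#' Magnitude of the vector sum of residue hydrophobicities placed at
#' `angle` degrees per residue around the helical wheel, divided by the
#' peptide length: `muH = |sum_k h_k exp(i k delta)| / N`. At the default
#' 100 degrees this is the standard alpha-helical hydrophobic moment and
#' serves as the amphipathicity index.
#'
#' @inheritParams mean_hydrophobicity
#' @param angle Rotation per residue in degrees (default 100).
#' @return Numeric vector of hydrophobic moments.
#' @export
hydrophobic_moment <- function(peptides, scale = NULL, angle = 100) {
  scale <- scale %||% hydrophobicity_values()
  delta <- angle * pi / 180
  vapply(peptides, function(p) {
    h <- scale[aa_chars(p)]
    if (any(is.na(h))) {
      abort(sprintf("Residue missing from hydrophobicity scale in '%s'.", p))
    }
    k <- seq_along(h)
    sqrt(sum(h * cos(k * delta))^2 + sum(h * sin(k * delta))^2) / length(h)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water mass. Average masses by default;
#' monoisotopic via `kind`.
#'
#' @param peptides Character vector of peptide sequences.
#' @param kind `"average"` (default) or `"monoisotopic"`.
#' @return Numeric vector of masses in Daltons.
#' @examples
#' molecular_weight("G")  # glycine residue + water, 75.07 Da
#' @export
molecular_weight <- function(peptides, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- read_resource("residue_masses.tsv")
  masses <- setNames(tab[[kind]], tab$residue)
  water <- if (kind == "average") 18.01524 else 18.010565
  vapply(peptides, function(p) {
    m <- masses[aa_chars(p)]
    if (any(is.na(m))) {
      abort(sprintf("Residue missing from mass table in '%s'.", p))
    }
    sum(m) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical property profile of peptides
#'
#' Convenience wrapper producing the descriptors commonly reported for
#' antimicrobial peptide sets: length, net charge at the stated pH,
#' isoelectric point, mean hydrophobicity, amphipathicity (hydrophobic
#' moment at 100 degrees) and molecular weight.
#'
#' @param peptides Character vector or tibble with a `peptide` column.
#' @param pH pH for the net charge (default 7).
#' @param mass_kind `"average"` or `"monoisotopic"`.
#' @return Tibble with one row per peptide.
#' @export
peptide_properties <- function(peptides, pH = 7,
                               mass_kind = c("average", "monoisotopic")) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  mass_kind <- match.arg(mass_kind)
  tibble(
    peptide = peptides,
    length = nchar(peptides),
    net_charge = net_charge(peptides, pH = pH),
    pI = isoelectric_point(peptides),
    hydrophobicity = mean_hydrophobicity(peptides),
    amphipathicity = hydrophobic_moment(peptides),
    mw = molecular_weight(peptides, kind = mass_kind)
  )
}
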