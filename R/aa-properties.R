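#' Amino-acid physicochemical property table
#'
#' Eight per-residue physicochemical scales used by the autocorrelation,
#' quasi-sequence-order (QSO) and amphiphilic pseudo amino-acid composition
#' (APAAC) descriptor families. Scales are classical literature values:
#' Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, residue mass
#' (average, Da), Zamyatnin residue volume (A^3), Grantham polarity,
#' isoelectric point, side-chain net charge at pH 7 and Charton
#' polarizability.
#'
#' @param standardize If `TRUE` (default), each scale is standardized to
#'   mean 0 and unit standard deviation across the 20 residues, the form the
#'   descriptor formulas consume.
#' @return A tibble with one row per amino acid (column `aa`, in the fixed
#'   alphabet order) and one column per property.
#' @export
#' @examples
#' aa_properties()
aa_properties <- function(standardize = TRUE) {
  tbl <- tibble::tibble(
    aa = AA20,
    hydropathy = c(
      1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
      1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3
    ),
    hydrophilicity = c(
      -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
      -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3
    ),
    residue_mass = c(
      71.08, 103.14, 115.09, 129.12, 147.18, 57.05, 137.14, 113.16, 128.17, 113.16,
      131.19, 114.10, 97.12, 128.13, 156.19, 87.08, 101.10, 99.13, 186.21, 163.18
    ),
    volume = c(
      88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6, 166.7,
      162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0, 227.8, 193.6
    ),
    polarity = c(
      8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
      5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2
    ),
    isoelectric_point = c(
      6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
      5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 5.96, 5.89, 5.66
    ),
    net_charge = c(
      0, 0, -1, -1, 0, 0, 0.1, 0, 1, 0,
      0, 0, 0, 0, 1, 0, 0, 0, 0, 0
    ),
    polarizability = c(
      0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186, 0.219, 0.186,
      0.221, 0.134, 0.131, 0.180, 0.291, 0.062, 0.108, 0.140, 0.409, 0.298
    )
  )
  if (standardize) {
    tbl <- dplyr::mutate(
      tbl,
      dplyr::across(-"aa", ~ (.x - mean(.x)) / stats::sd(.x))
    )
  }
  tbl
}

#' Physicochemical amino-acid distance matrix
#'
#' A 20 x 20 distance matrix between amino acids used for the
#' sequence-order-coupling terms of the QSO descriptors. Following the
#' Schneider-Wrede construction, the distance between residues i and j is the
#' root-mean-square difference of standardized hydropathy, hydrophilicity and
#' residue mass.
#'
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   20 amino-acid letters.
#' @export
#' @examples
#' d <- aa_distance_matrix()
#' all(diag(d) == 0)
aa_distance_matrix <- function() {
  props <- aa_properties(standardize = TRUE)
  p <- as.matrix(props[, c("hydropathy", "hydrophilicity", "residue_mass")])
  rownames(p) <- props$aa
  d <- as.matrix(stats::dist(p, method = "euclidean")) / sqrt(ncol(p))
  d[AA20, AA20]
}
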