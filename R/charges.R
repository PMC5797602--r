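# Composition-based charge arithmetic. At physiological pH the charged
# residue classes are D/E (-1) and K/R (+1); histidine and the chain termini
# are treated as neutral by default, and the per-class charge map can be
# overridden.

#' Charged-residue composition table
#'
#' @param D,E,K,R non-negative counts of aspartate, glutamate, lysine and
#'   arginine residues.
#' @param charge_map named numeric vector of per-class charges
#'   (default `c(D = -1, E = -1, K = +1, R = +1)`).
#' @return an object of class `"composition_table"`.
#' @export
composition_table <- function(D = 0, E = 0, K = 0, R = 0,
                              charge_map = c(D = -1, E = -1, K = 1, R = 1)) {
  counts <- c(D = D, E = E, K = K, R = R)
  if (any(counts < 0)) stop("residue counts must be non-negative")
  if (any(counts != round(counts))) stop("residue counts must be integers")
  structure(list(counts = counts, charge_map = charge_map),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition> D %d, E %d, K %d, R %d -> net %+g e\n",
              x$counts["D"], x$counts["E"], x$counts["K"], x$counts["R"],
              net_charge(x)))
  invisible(x)
}

#' Net charge of a charged-residue composition
#'
#' With the default charge map this is `-(D + E) + (K + R)` elementary
#' charges; e.g. the 284-residue disordered chain with 47 D, 24 E, 18 K and
#' 9 R carries net charge -44 at physiological pH.
#'
#' @param composition a [composition_table()].
#' @return signed number, elementary charges.
#' @export
net_charge <- function(composition) {
  stopifnot(inherits(composition, "composition_table"))
  cm <- composition$charge_map[names(composition$counts)]
  sum(composition$counts * cm)
}

#' Bare charges of a protein-RNA pair
#'
#' The RNA carries one phosphate (-1 e) per internucleotide linkage, i.e.
#' `-(n_nt - 1)` for an `n_nt`-mer without a 5'-terminal phosphate (the
#' default); a 40-mer therefore contributes -39, and with a -44 protein the
#' complex's total bare charge is -83.
#'
#' @param n_nt number of nucleotides (>= 1).
#' @param composition protein [composition_table()].
#' @param five_prime_phosphate if `TRUE`, the 5' terminus carries a
#'   phosphate too (RNA charge `-n_nt`).
#' @return named numeric vector `c(protein, rna, total)`, elementary charges.
#' @export
bare_charges <- function(n_nt, composition, five_prime_phosphate = FALSE) {
  if (n_nt < 1) stop("n_nt must be >= 1")
  qp <- net_charge(composition)
  qr <- -(n_nt - if (five_prime_phosphate) 0L else 1L)
  c(protein = qp, rna = qr, total = qp + qr)
}
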