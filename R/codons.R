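#' Codon universe helpers
#'
#' The occupancy tables always span all 64 codons; the simulator's codon-usage
#' vector spans the 61 sense codons (stop codons are never drawn as sense
#' positions). Codons are uppercase DNA triplets in alphabetical order.
#'
#' @return `all_codons()`: character vector of the 64 codons;
#'   `sense_codons()`: the 61 sense codons; `stop_codons()`: `TAA`, `TAG`,
#'   `TGA`.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

#' @rdname all_codons
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' @rdname all_codons
#' @export
sense_codons <- function() setdiff(all_codons(), stop_codons())

#' Codons decoded by one amino acid
#'
#' Looks up the standard genetic code, e.g. `codon_family("G")` returns the
#' glycine family `GGA, GGC, GGG, GGT` — the codons read by glycyl-tRNA.
#'
#' @param amino_acid single-letter amino-acid code (or `"*"` for stops).
#' @return character vector of codons.
#' @export
codon_family <- function(amino_acid) {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc == amino_acid])
}

#' Codon-usage vectors for the simulator
#'
#' `codon_usage_uniform()` gives equal mass to the 61 sense codons.
#' `codon_usage_with_family()` rescales one codon group to a chosen total
#' mass, splitting the mass equally within the group and renormalizing the
#' remaining codons, e.g. glycine-family mass 0.01 for a rare-codon scenario.
#'
#' @param family codons forming the group.
#' @param mass total probability assigned to the group (0 < mass < 1).
#' @param base usage vector to modify (default uniform).
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
codon_usage_uniform <- function() {
  sc <- sense_codons()
  setNames(rep(1 / length(sc), length(sc)), sc)
}

#' @rdname codon_usage_uniform
#' @export
codon_usage_with_family <- function(family, mass, base = codon_usage_uniform()) {
  stopifnot(all(family %in% names(base)), mass > 0, mass < 1)
  out <- base
  out[family] <- mass / length(family)
  rest <- setdiff(names(base), family)
  out[rest] <- base[rest] / sum(base[rest]) * (1 - mass)
  out
}
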