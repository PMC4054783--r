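# Genetic-code lookups shared by the codon and divergence analyses.
# The code table itself comes from Biostrings; everything here is derived.

.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    tab <- Biostrings::GENETIC_CODE
    .codon_env$tab <- tab
  }
  .codon_env$tab
}

#' Sense codons of the standard genetic code
#'
#' @return character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

#' @rdname sense_codons
#' @return `stop_codons` returns the three stop codons.
#' @export
stop_codons <- function() {
  tab <- codon_table()
  names(tab)[tab == "*"]
}

#' Four-fold degenerate codon families
#'
#' A four-fold family is a codon prefix (first two bases) for which all four
#' third bases encode the same amino acid; third positions of such codons
#' are fully synonymous. There are eight families in the standard code.
#'
#' @return character vector of the two-base family prefixes.
#' @export
fourfold_families <- function() {
  if (is.null(.codon_env$ff)) {
    tab <- codon_table()
    pref <- substr(names(tab), 1, 2)
    ff <- vapply(unique(pref), function(p) {
      aa <- tab[pref == p]
      length(unique(aa)) == 1 && all(aa != "*")
    }, logical(1))
    .codon_env$ff <- sort(names(ff)[ff])
  }
  .codon_env$ff
}

#' Is a codon a member of a four-fold degenerate family?
#'
#' @param codon character vector of codons.
#' @return logical vector.
#' @export
is_fourfold <- function(codon) {
  substr(toupper(codon), 1, 2) %in% fourfold_families() &
    !grepl("[^ACGT]", codon)
}

#' Translate codons to amino acids
#'
#' @param codons character vector of codons; `"---"` gaps and codons with
#'   ambiguous bases return `NA`.
#' @return character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  unname(codon_table()[toupper(codons)])
}

#' All synonymous codon pairs
#'
#' All unordered pairs of sense codons encoding the same amino acid (stop
#' codons excluded): 87 pairs in the standard code.
#'
#' @return data.frame with columns `codon1`, `codon2`, `aa`.
#' @export
synonymous_pairs <- function() {
  tab <- codon_table()
  tab <- tab[tab != "*"]
  out <- lapply(unique(tab), function(aa) {
    cods <- sort(names(tab)[tab == aa])
    if (length(cods) < 2) return(NULL)
    cb <- utils::combn(cods, 2)
    data.frame(codon1 = cb[1, ], codon2 = cb[2, ], aa = aa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$aa, out$codon1, out$codon2), , drop = FALSE]
}
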