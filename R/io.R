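# Readers for the remaining external formats; all small and line-oriented.

#' Read a SNP table
#'
#' Two-column TSV (`exon_id`, `offset`) with 0-based offsets; duplicate
#' positions are collapsed (the analyses use the proportion of sites with
#' at least one SNP, not SNP counts).
#'
#' @param path file path.
#' @return data.frame with `exon_id`, `offset`.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("exon_id", "offset") %in% names(tab))) {
    stop("SNP table needs 'exon_id' and 'offset' columns")
  }
  unique(tab[, c("exon_id", "offset")])
}

#' Read paired ortholog alignments from FASTA
#'
#' Reads a gapped peptide alignment FASTA (two records per pair, grouped by
#' a shared identifier prefix before the first `|`) together with the two
#' ungapped CDS FASTAs, and back-translates each pair to a codon alignment
#' via [backtranslate_alignment()].
#'
#' @param pep_fasta path to the aligned peptide FASTA (records `id|sp1`,
#'   `id|sp2`).
#' @param cds_fasta1,cds_fasta2 paths to the CDS FASTAs (records named by
#'   `id`).
#' @return data.frame with `gene_id`, `seq1`, `seq2` (codon alignments).
#' @export
read_ortholog_alignments <- function(pep_fasta, cds_fasta1, cds_fasta2) {
  peps <- Biostrings::readAAStringSet(pep_fasta)
  cds1 <- Biostrings::readDNAStringSet(cds_fasta1)
  cds2 <- Biostrings::readDNAStringSet(cds_fasta2)
  ids <- sub("\\|.*$", "", names(peps))
  sp <- sub("^[^|]*\\|", "", names(peps))
  out <- lapply(unique(ids), function(id) {
    sel <- which(ids == id)
    if (length(sel) != 2) stop("pair '", id, "' does not have two records")
    p1 <- as.character(peps[[sel[order(sp[sel])[1]]]])
    p2 <- as.character(peps[[sel[order(sp[sel])[2]]]])
    aln <- backtranslate_alignment(p1, p2, as.character(cds1[[id]]),
                                   as.character(cds2[[id]]))
    data.frame(gene_id = id, seq1 = aln$seq1, seq2 = aln$seq2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a data.frame as TSV
#'
#' Plain tab-separated output with a header, used for all table-shaped
#' reports.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
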