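#' Build and validate an exon table
#'
#' The exon table is the central container for positional and association
#' analyses: one row per internal exon, sense-strand sequences only
#' (minus-strand genes must be reverse-complemented upstream; no strand
#' logic exists downstream). Coordinates are 1-based inclusive in all
#' reports; distances from a splice site count the first exonic base as
#' distance 1.
#'
#' @param exons data.frame with at least `exon_id` and `exon_seq`; optional
#'   columns: `gene_id`, `up_intron_seq`, `down_intron_seq`,
#'   `up_intron_len`, `down_intron_len`, `score5`, `score3`,
#'   `alternative` (logical), `conserved` (logical), `coding` (logical).
#' @return the validated data.frame (invisibly classed `"exon_table"`).
#' @export
exon_table <- function(exons) {
  stopifnot(is.data.frame(exons))
  req <- c("exon_id", "exon_seq")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  exons$exon_seq <- toupper(exons$exon_seq)
  if (any(nchar(exons$exon_seq) < 1)) stop("empty exon sequence")
  if (any(grepl("[^ACGTN]", exons$exon_seq))) {
    stop("exon sequences must be over ACGTN")
  }
  for (col in c("up_intron_seq", "down_intron_seq")) {
    if (col %in% names(exons)) exons[[col]] <- toupper(exons[[col]])
  }
  for (col in c("up_intron_len", "down_intron_len")) {
    seqcol <- sub("_len$", "_seq", col)
    if (col %in% names(exons) && seqcol %in% names(exons)) {
      short <- !is.na(exons[[col]]) &
        exons[[col]] < nchar(exons[[seqcol]])
      if (any(short)) stop("intron length smaller than stored intron sequence")
    }
  }
  class(exons) <- c("exon_table", "data.frame")
  exons
}

#' Read an exon table from TSV
#'
#' Tab-separated with a header; columns as in [exon_table()].
#'
#' @param path file path.
#' @return an [exon_table()].
#' @export
read_exon_table <- function(path) {
  exon_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Mask positions covered by ESE motifs
#'
#' Position i is `TRUE` iff it is covered by at least one occurrence of any
#' motif in the set (all six positions of each match are flagged).
#' Ambiguous bases (N) break matches and are never flagged.
#'
#' @param seq a single DNA string over ACGTN.
#' @param set a [hexamer_set()] (or character vector of hexamers).
#' @return logical vector of length `nchar(seq)`.
#' @examples
#' which(mask_ese_positions("AAGAAGAA", hexamer_set("GAAGAA"))) # 3..8
#' @export
mask_ese_positions <- function(seq, set) {
  seq <- toupper(seq)
  L <- nchar(seq)
  mask <- logical(L)
  if (L < 6 || length(set) == 0) return(mask)
  starts <- seq_len(L - 5L)
  words <- substring(seq, starts, starts + 5L)
  hit <- starts[words %in% as.character(set)]
  for (off in 0:5) mask[hit + off] <- TRUE
  mask
}

#' Composite intron-exon-intron profile sequence
#'
#' Builds the merged sequence used for boundary-density profiling: the last
#' 100 nt of the upstream intron, the exon contribution, and the first 100
#' nt of the downstream intron. The exon contributes its first and last 50
#' nt, plus its central 100 nt when longer than 200 nt; for exons of 51-100
#' nt the two 50-nt windows overlap and overlapping positions are emitted
#' once (the whole exon is used), avoiding double counting.
#'
#' @param exon_seq exon sequence (> 50 nt).
#' @param up_intron_seq,down_intron_seq flanking intron sequences with at
#'   least `flank` nt available.
#' @param flank intron flank width (default 100 nt).
#' @return A list with `seq` (the composite string), `region` (factor per
#'   position: `intron5`, `exon_start`, `exon_core`, `exon_end`, `intron3`)
#'   and `distance` (1-based distance from the nearest splice site, measured
#'   into the position's own region).
#' @export
merged_profile_sequence <- function(exon_seq, up_intron_seq, down_intron_seq,
                                    flank = 100) {
  exon_seq <- toupper(exon_seq)
  L <- nchar(exon_seq)
  if (L <= 50) stop("exon must be longer than 50 nt")
  if (nchar(up_intron_seq) < flank || nchar(down_intron_seq) < flank) {
    stop("insufficient flanking intron sequence")
  }
  up <- substr(toupper(up_intron_seq),
               nchar(up_intron_seq) - flank + 1L, nchar(up_intron_seq))
  down <- substr(toupper(down_intron_seq), 1L, flank)
  if (L <= 100) {
    ex <- exon_seq
    ex_region <- ifelse(seq_len(L) <= ceiling(L / 2), "exon_start", "exon_end")
    ex_dist <- pmin(seq_len(L), L - seq_len(L) + 1L)
  } else if (L <= 200) {
    ex <- paste0(substr(exon_seq, 1, 50), substr(exon_seq, L - 49L, L))
    ex_region <- rep(c("exon_start", "exon_end"), each = 50)
    ex_dist <- c(1:50, 50:1)
  } else {
    mid0 <- floor((L - 100) / 2)
    core <- substr(exon_seq, mid0 + 1L, mid0 + 100L)
    ex <- paste0(substr(exon_seq, 1, 50), core, substr(exon_seq, L - 49L, L))
    ex_region <- rep(c("exon_start", "exon_core", "exon_end"), c(50, 100, 50))
    core_pos <- (mid0 + 1L):(mid0 + 100L)
    ex_dist <- c(1:50, pmin(core_pos, L - core_pos + 1L), 50:1)
  }
  region <- factor(
    c(rep("intron5", flank), ex_region, rep("intron3", flank)),
    levels = c("intron5", "exon_start", "exon_core", "exon_end", "intron3"))
  distance <- c(rev(seq_len(flank)), ex_dist, seq_len(flank))
  list(seq = paste0(up, ex, down), region = region, distance = distance)
}

#' Back-translate a peptide alignment to a codon alignment
#'
#' Uses a gapped peptide alignment as the template to reconstruct the
#' nucleotide alignment from the original CDS nucleotides: each residue is
#' replaced by its source codon, each peptide gap by `"---"`.
#'
#' @param pep1,pep2 aligned (gapped) peptide strings of equal length.
#' @param cds1,cds2 ungapped CDS DNA whose translation must match the
#'   ungapped peptides exactly (standard code; a trailing stop codon on the
#'   CDS is tolerated).
#' @return list with `seq1`, `seq2`: aligned codon strings (length a
#'   multiple of 3, equal codon counts).
#' @export
backtranslate_alignment <- function(pep1, pep2, cds1, cds2) {
  one <- function(pep, cds, label) {
    pep <- toupper(pep)
    cds <- toupper(cds)
    res <- strsplit(pep, "")[[1]]
    n_res <- sum(res != "-")
    if (nchar(cds) < 3 * n_res) stop("CDS shorter than peptide for ", label)
    codons <- substring(cds, 3 * seq_len(n_res) - 2, 3 * seq_len(n_res))
    aa <- translate_codons(codons)
    mism <- which(aa != res[res != "-"])
    if (length(mism)) {
      stop(sprintf(
        "translation mismatch in %s at residue %d: codon %s is %s, peptide has %s",
        label, mism[1], codons[mism[1]], aa[mism[1]],
        res[res != "-"][mism[1]]))
    }
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- codons
    paste(out, collapse = "")
  }
  if (nchar(pep1) != nchar(pep2)) stop("aligned peptides differ in length")
  list(seq1 = one(pep1, cds1, "seq1"), seq2 = one(pep2, cds2, "seq2"))
}

#' Analysable four-fold degenerate third positions of a codon alignment
#'
#' Returns 1-based nucleotide offsets (within the aligned sequences) of
#' third positions of aligned codon pairs where both codons are ungapped,
#' both belong to a four-fold degenerate family, and the family (first two
#' bases) is identical in the two species. Only at such sites is any
#' third-position difference guaranteed synonymous in both species.
#'
#' @param pair list with `seq1`, `seq2`: aligned codon strings (equal
#'   length, multiple of 3; gaps as `"---"`).
#' @return integer vector of third-position offsets.
#' @export
fourfold_sites <- function(pair) {
  s1 <- toupper(pair$seq1)
  s2 <- toupper(pair$seq2)
  if (nchar(s1) != nchar(s2)) stop("aligned sequences differ in length")
  if (nchar(s1) %% 3 != 0) stop("alignment length must be a multiple of 3")
  n <- nchar(s1) %/% 3
  if (n == 0) return(integer(0))
  st <- 3L * seq_len(n) - 2L
  c1 <- substring(s1, st, st + 2L)
  c2 <- substring(s2, st, st + 2L)
  ok <- is_fourfold(c1) & is_fourfold(c2) &
    substr(c1, 1, 2) == substr(c2, 1, 2)
  st[ok] + 2L
}

#' Filter gene pairs down to analysable orthologous internal exon pairs
#'
#' Applies, in order: one-to-one orthologs only; duplicate gene identifiers
#' resolved to the longest first-species transcript (ties broken by the
#' longest second-species transcript); CDS sanity (starts ATG, ends with a
#' stop codon, length a multiple of 3, no internal stops, ACGT only, exon
#' boundaries inside the CDS); equal exon counts in the two species; every
#' orthologous internal exon pair within 5% length difference (first
#' species' length as denominator) — violating genes are removed; first and
#' last exons dropped; remaining exon boundaries trimmed to codon frame.
#'
#' @param genes a list of gene records; each record a list with `gene_id`,
#'   `ortholog_type` (keep `"one2one"`), and `sp1`, `sp2` each a list with
#'   `cds` (string) and `exon_lens` (integer vector partitioning the CDS).
#' @param max_len_diff maximum tolerated relative exon length difference
#'   (default 0.05).
#' @return list with `pairs` — a data.frame (gene_id, exon_index, seq1,
#'   seq2: frame-trimmed unaligned exon CDS chunks) — and `tally`, the
#'   per-filter rejection counts.
#' @export
filter_ortholog_exons <- function(genes, max_len_diff = 0.05) {
  tally <- c(not_one2one = 0L, duplicate = 0L, bad_cds = 0L,
             exon_count_mismatch = 0L, exon_length_diff = 0L,
             malformed_structure = 0L, retained = 0L)
  keep <- list()
  # one2one filter
  for (g in genes) {
    if (!identical(g$ortholog_type, "one2one")) {
      tally["not_one2one"] <- tally["not_one2one"] + 1L
    } else keep[[length(keep) + 1L]] <- g
  }
  # duplicate resolution: longest sp1 transcript, ties -> longest sp2
  ids <- vapply(keep, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) {
    chosen <- logical(length(keep))
    for (id in unique(ids)) {
      idx <- which(ids == id)
      if (length(idx) == 1) { chosen[idx] <- TRUE; next }
      l1 <- vapply(keep[idx], function(g) nchar(g$sp1$cds), integer(1))
      best <- idx[l1 == max(l1)]
      if (length(best) > 1) {
        l2 <- vapply(keep[best], function(g) nchar(g$sp2$cds), integer(1))
        best <- best[which.max(l2)]
      } else best <- best[1]
      chosen[best] <- TRUE
      tally["duplicate"] <- tally["duplicate"] + (length(idx) - 1L)
    }
    keep <- keep[chosen]
  }
  stops <- stop_codons()
  cds_ok <- function(cds, exon_lens) {
    cds <- toupper(cds)
    n <- nchar(cds)
    if (sum(exon_lens) != n || any(exon_lens <= 0)) return("malformed")
    if (grepl("[^ACGT]", cds)) return("bad")
    if (n %% 3 != 0) return("bad")
    if (substr(cds, 1, 3) != "ATG") return("bad")
    cods <- substring(cds, 3 * seq_len(n %/% 3) - 2, 3 * seq_len(n %/% 3))
    if (!(cods[length(cods)] %in% stops)) return("bad")
    if (any(cods[-length(cods)] %in% stops)) return("bad")
    "ok"
  }
  pairs <- list()
  for (g in keep) {
    st1 <- cds_ok(g$sp1$cds, g$sp1$exon_lens)
    st2 <- cds_ok(g$sp2$cds, g$sp2$exon_lens)
    if (st1 == "malformed" || st2 == "malformed") {
      tally["malformed_structure"] <- tally["malformed_structure"] + 1L
      next
    }
    if (st1 == "bad" || st2 == "bad") {
      tally["bad_cds"] <- tally["bad_cds"] + 1L
      next
    }
    n1 <- length(g$sp1$exon_lens)
    n2 <- length(g$sp2$exon_lens)
    if (n1 != n2) {
      tally["exon_count_mismatch"] <- tally["exon_count_mismatch"] + 1L
      next
    }
    if (n1 < 3) next  # no internal exons
    internal <- 2:(n1 - 1)
    l1 <- g$sp1$exon_lens[internal]
    l2 <- g$sp2$exon_lens[internal]
    if (any(abs(l1 - l2) > max_len_diff * l1)) {
      tally["exon_length_diff"] <- tally["exon_length_diff"] + 1L
      next
    }
    tally["retained"] <- tally["retained"] + 1L
    ends1 <- cumsum(g$sp1$exon_lens)
    ends2 <- cumsum(g$sp2$exon_lens)
    for (i in internal) {
      tr1 <- .frame_trim(toupper(g$sp1$cds), ends1[i - 1] + 1L, ends1[i])
      tr2 <- .frame_trim(toupper(g$sp2$cds), ends2[i - 1] + 1L, ends2[i])
      if (is.null(tr1) || is.null(tr2)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = g$gene_id, exon_index = i, seq1 = tr1, seq2 = tr2,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_id = character(0), exon_index = integer(0),
               seq1 = character(0), seq2 = character(0))
  list(pairs = pairs, tally = tally)
}

# trim a CDS slice [start, end] (1-based) inward to whole-codon boundaries
.frame_trim <- function(cds, start, end) {
  s <- start + (3L - (start - 1L) %% 3L) %% 3L
  e <- end - end %% 3L
  if (e - s + 1L < 3L) return(NULL)
  substr(cds, s, e)
}
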