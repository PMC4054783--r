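# Positional ESE density profiling over the composite
# intron | exon ends (+ core) | intron layout, and region-contrast tests.

# internal: composite mask + coordinate map for each qualifying exon
.composite_masks <- function(exons, set, flank = 100) {
  stopifnot(is.data.frame(exons))
  out <- vector("list", nrow(exons))
  kept <- logical(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    res <- tryCatch(
      merged_profile_sequence(exons$exon_seq[i], exons$up_intron_seq[i],
                              exons$down_intron_seq[i], flank = flank),
      error = function(e) NULL)
    if (is.null(res)) next
    kept[i] <- TRUE
    res$mask <- mask_ese_positions(res$seq, set)
    out[[i]] <- res
  }
  n_skip <- sum(!kept)
  if (n_skip > 0) {
    message(sprintf("%d exon(s) skipped (short exon or missing intron flank)",
                    n_skip))
  }
  out[kept]
}

#' Positional ESE coverage profile
#'
#' For each composite coordinate (region and distance from the nearest
#' splice site) the fraction of contributing exons whose ESE mask is true
#' there. Coverage is the fraction of nucleotide positions covered by at
#' least one motif occurrence.
#'
#' @param exons an [exon_table()] with intron flank sequences.
#' @param set a [hexamer_set()].
#' @param flank intron flank width in nt.
#' @return data.frame with columns `region`, `distance`, `n` (contributing
#'   exons) and `coverage`.
#' @export
profile_density <- function(exons, set, flank = 100) {
  comps <- .composite_masks(exons, set, flank)
  if (length(comps) == 0) stop("no exon qualifies for profiling")
  region <- unlist(lapply(comps, function(x) as.character(x$region)))
  distance <- unlist(lapply(comps, function(x) x$distance))
  masked <- unlist(lapply(comps, function(x) x$mask))
  key <- interaction(region, distance, drop = TRUE)
  agg <- data.frame(
    region = tapply(region, key, `[`, 1),
    distance = as.integer(tapply(distance, key, `[`, 1)),
    n = as.integer(tapply(masked, key, length)),
    coverage = as.numeric(tapply(masked, key, mean)),
    row.names = NULL, stringsAsFactors = FALSE)
  agg$region <- factor(agg$region, levels = c("intron5", "exon_start",
                                              "exon_core", "exon_end",
                                              "intron3"))
  agg[order(agg$region, agg$distance), , drop = FALSE]
}

#' Per-exon region densities and region-contrast tests
#'
#' Coverage density per exon in four regions of the composite layout —
#' intron (both 100-nt flanks pooled), exon (the exon contribution), ends
#' (the two 50-nt exonic flank windows) and core (central 100 nt, exons
#' longer than 200 nt only). Unpaired two-sided Mann-Whitney tests contrast
#' exon vs intron and ends vs core across exons. Per-hexamer normalisation
#' (density divided by catalogue size) is reported alongside, both as the
#' median density over size and as the median of per-exon per-hexamer
#' densities (these can differ; both are emitted).
#'
#' @inheritParams profile_density
#' @return list with `per_exon` (data.frame of per-exon densities),
#'   `medians`, `medians_per_hexamer`, `median_of_per_hexamer`,
#'   `p_exon_vs_intron`, `p_ends_vs_core`.
#' @export
region_densities <- function(exons, set, flank = 100) {
  comps <- .composite_masks(exons, set, flank)
  if (length(comps) == 0) stop("no exon qualifies")
  per <- do.call(rbind, lapply(comps, function(x) {
    r <- x$region
    m <- x$mask
    data.frame(
      intron = mean(m[r %in% c("intron5", "intron3")]),
      exon = mean(m[r %in% c("exon_start", "exon_core", "exon_end")]),
      ends = mean(m[r %in% c("exon_start", "exon_end")]),
      core = if (any(r == "exon_core")) mean(m[r == "exon_core"]) else
        NA_real_)
  }))
  meds <- vapply(per, stats::median, numeric(1), na.rm = TRUE)
  size <- max(length(set), 1L)
  p_ei <- suppressWarnings(stats::wilcox.test(per$exon, per$intron))$p.value
  core_ok <- !is.na(per$core)
  p_ec <- if (sum(core_ok) >= 2) {
    suppressWarnings(
      stats::wilcox.test(per$ends[core_ok], per$core[core_ok]))$p.value
  } else NA_real_
  list(per_exon = per,
       medians = meds,
       medians_per_hexamer = meds / size,
       median_of_per_hexamer = vapply(per, function(v)
         stats::median(v / size, na.rm = TRUE), numeric(1)),
       p_exon_vs_intron = p_ei,
       p_ends_vs_core = p_ec)
}

#' Paired flank-vs-core density test (exons > 200 nt)
#'
#' Within each exon longer than 200 nt, the flank density (the two terminal
#' 50-nt windows pooled) is compared with the core density (the central
#' 100 nt) of the same exon, removing between-exon composition confounding.
#' Masks are computed on the intact exon sequence. Returns the one-tailed
#' paired Wilcoxon signed-rank P (alternative: flank > core) and the
#' binomial sign-test P over the signs of flank - core, zero differences
#' dropped.
#'
#' @param exons an [exon_table()]; only rows with exon length > 200 nt are
#'   used.
#' @param set a [hexamer_set()].
#' @param min_exons minimum number of qualifying exons.
#' @return list with `n`, `p_wilcoxon`, `p_sign`, `median_flank`,
#'   `median_core`.
#' @export
paired_flank_core_test <- function(exons, set, min_exons = 10) {
  lens <- nchar(exons$exon_seq)
  use <- which(lens > 200)
  if (length(use) < min_exons) {
    stop(sprintf("only %d exon(s) longer than 200 nt (need >= %d)",
                 length(use), min_exons))
  }
  flank <- core <- numeric(length(use))
  for (j in seq_along(use)) {
    i <- use[j]
    L <- lens[i]
    m <- mask_ese_positions(exons$exon_seq[i], set)
    mid0 <- floor((L - 100) / 2)
    flank[j] <- mean(m[c(1:50, (L - 49L):L)])
    core[j] <- mean(m[(mid0 + 1L):(mid0 + 100L)])
  }
  d <- flank - core
  if (all(d == 0)) {
    warning("all flank-core differences are zero")
    return(list(n = length(d), p_wilcoxon = 1, p_sign = 1,
                median_flank = stats::median(flank),
                median_core = stats::median(core)))
  }
  nz <- d[d != 0]
  pw <- stats::wilcox.test(flank, core, paired = TRUE,
                           alternative = "greater",
                           exact = length(nz) < 25,
                           correct = TRUE)$p.value
  ps <- stats::binom.test(sum(nz > 0), length(nz),
                          alternative = "greater")$p.value
  list(n = length(d), p_wilcoxon = pw, p_sign = ps,
       median_flank = stats::median(flank), median_core = stats::median(core))
}

#' Purine content inside and outside ESEs at exon flanks
#'
#' Within the terminal 50 nt at both exon ends, the purine (A or G)
#' fraction over ESE-masked positions and over unmasked positions, per
#' exon; cross-exon means and medians of each. An exon with an empty masked
#' (or unmasked) flank contributes only to the defined side.
#'
#' @param exons an [exon_table()].
#' @param set a [hexamer_set()].
#' @param flank_width flank window width per end (default 50 nt).
#' @return list with `mean_ese`, `mean_non`, `median_ese`, `median_non`,
#'   `per_exon` (data.frame with `purine_ese`, `purine_non`).
#' @export
flank_purine_split <- function(exons, set, flank_width = 50) {
  pe <- pn <- rep(NA_real_, nrow(exons))
  for (i in seq_len(nrow(exons))) {
    s <- exons$exon_seq[i]
    L <- nchar(s)
    idx <- unique(c(seq_len(min(flank_width, L)),
                    (max(1L, L - flank_width + 1L)):L))
    m <- mask_ese_positions(s, set)[idx]
    ch <- strsplit(substring(s, 1, L), "")[[1]][idx]
    valid <- ch %in% c("A", "C", "G", "T")
    pur <- ch %in% c("A", "G")
    if (any(m & valid)) pe[i] <- mean(pur[m & valid])
    if (any(!m & valid)) pn[i] <- mean(pur[!m & valid])
  }
  list(mean_ese = mean(pe, na.rm = TRUE), mean_non = mean(pn, na.rm = TRUE),
       median_ese = stats::median(pe, na.rm = TRUE),
       median_non = stats::median(pn, na.rm = TRUE),
       per_exon = data.frame(purine_ese = pe, purine_non = pn))
}
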