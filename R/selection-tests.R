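# Divergence and SNP-density contrasts between ESE, non-ESE and
# composition-matched pseudoESE sites, by distance from the exon boundary.

#' Four-fold site divergence by distance from the exon boundary
#'
#' Each exon is split in two at its midpoint; every analysable four-fold
#' degenerate third position (see [fourfold_sites()]) is classified ESE or
#' non-ESE by the first-species (human) mask at that position, and tallied
#' as substituted when the two species differ there. Distances are in nt
#' from the nearest splice junction (first exonic base = 1), truncated at
#' `min(half-exon length, max_distance)`.
#'
#' @param pairs data.frame with columns `seq1`, `seq2` (aligned codon
#'   strings, equal length, gaps `"---"`), e.g. from
#'   [filter_ortholog_exons()] + [backtranslate_alignment()] or
#'   [gen_ortholog_pairs()].
#' @param set a [hexamer_set()]; the mask is computed on `seq1` only.
#' @param max_distance distance cap in nt.
#' @return data.frame per distance: `distance`, `sites_ese`, `subst_ese`,
#'   `sites_non`, `subst_non`, `prop_ese`, `prop_non`. Empty (with a
#'   warning) when no four-fold site is analysable.
#' @export
divergence_by_distance <- function(pairs, set, max_distance = 100) {
  se <- sb_e <- sn <- sb_n <- integer(max_distance)
  for (i in seq_len(nrow(pairs))) {
    s1 <- toupper(pairs$seq1[i])
    s2 <- toupper(pairs$seq2[i])
    L <- nchar(s1)
    ff <- fourfold_sites(list(seq1 = s1, seq2 = s2))
    if (length(ff) == 0) next
    mask <- mask_ese_positions(s1, set)
    d <- pmin(ff, L - ff + 1L)
    keep <- d <= max_distance
    if (!any(keep)) next
    ff <- ff[keep]; d <- d[keep]
    ese <- mask[ff]
    sub <- substring(s1, ff, ff) != substring(s2, ff, ff)
    for (j in seq_along(ff)) {
      if (ese[j]) {
        se[d[j]] <- se[d[j]] + 1L
        if (sub[j]) sb_e[d[j]] <- sb_e[d[j]] + 1L
      } else {
        sn[d[j]] <- sn[d[j]] + 1L
        if (sub[j]) sb_n[d[j]] <- sb_n[d[j]] + 1L
      }
    }
  }
  if (sum(se) + sum(sn) == 0) {
    warning("no analysable four-fold degenerate site")
  }
  data.frame(distance = seq_len(max_distance),
             sites_ese = se, subst_ese = sb_e,
             sites_non = sn, subst_non = sb_n,
             prop_ese = ifelse(se > 0, sb_e / se, NA_real_),
             prop_non = ifelse(sn > 0, sb_n / sn, NA_real_))
}

#' Composition-matched random hexamer (pseudoESE) sets
#'
#' Replicate random catalogues whose hexamers have bases drawn i.i.d. from
#' a target composition, matching a real catalogue's average nucleotide
#' content; used as a mutability-controlled null. Duplicates within a set
#' are redrawn; members of the real set are not excluded (the pseudo pool
#' knowingly contains true motifs, which attenuates contrasts).
#'
#' @param composition numeric vector of base fractions named A, C, G, T
#'   (will be normalised), e.g. `base_composition(set)$fractions`.
#' @param size hexamers per replicate set.
#' @param replicates number of replicate sets (default 100).
#' @param seed integer seed.
#' @return list of [hexamer_set()] objects.
#' @export
pseudo_ese_sets <- function(composition, size, replicates = 100, seed) {
  if (missing(seed)) stop("'seed' is required")
  comp <- composition[c("A", "C", "G", "T")]
  stopifnot(!anyNA(comp), all(comp >= 0), sum(comp) > 0, size >= 1)
  comp <- comp / sum(comp)
  n_distinct <- sum(comp > 0)^6
  if (size > n_distinct) {
    stop("size exceeds the number of distinct hexamers attainable from ",
         "this composition")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  draw <- function(n) {
    m <- matrix(sample(bases, 6 * n, replace = TRUE, prob = comp),
                ncol = 6)
    apply(m, 1, paste0, collapse = "")
  }
  lapply(seq_len(replicates), function(r) {
    h <- unique(draw(size))
    while (length(h) < size) h <- unique(c(h, draw(size - length(h))))
    hexamer_set(h, name = sprintf("pseudo%03d", r))
  })
}

#' Paired-by-distance Wilcoxon test between two profiles
#'
#' Two-sided Wilcoxon signed-rank test over per-distance proportion pairs,
#' restricted to the shared distance support (rows where both profiles have
#' a defined proportion and at least `min_sites` classified sites in each
#' class compared).
#'
#' @param profile_a,profile_b profiles from [divergence_by_distance()] or
#'   [snp_profile()]; `cols` names the proportion column compared in each.
#' @param cols length-2 character: proportion column of `profile_a` and of
#'   `profile_b` (default compares `prop_ese` of A with `prop_non` of B —
#'   pass the same profile twice for the within-profile ESE vs non-ESE
#'   contrast).
#' @param min_sites minimum classified sites per distance cell (cells below
#'   are dropped; default 50).
#' @return list with `n_distances`, `p`, `median_a`, `median_b`.
#' @export
paired_distance_test <- function(profile_a, profile_b,
                                 cols = c("prop_ese", "prop_non"),
                                 min_sites = 50) {
  sites_col <- function(col) if (grepl("ese$", col)) "sites_ese" else
    "sites_non"
  m <- merge(profile_a, profile_b, by = "distance",
             suffixes = c("_a", "_b"))
  a <- m[[paste0(cols[1], "_a")]]
  b <- m[[paste0(cols[2], "_b")]]
  na <- m[[paste0(sites_col(cols[1]), "_a")]]
  nb <- m[[paste0(sites_col(cols[2]), "_b")]]
  keep <- !is.na(a) & !is.na(b) & na >= min_sites & nb >= min_sites
  a <- a[keep]; b <- b[keep]
  if (length(a) < 6) warning("fewer than 6 shared distances; exact test")
  if (length(a) == 0 || all(a == b)) {
    return(list(n_distances = length(a), p = 1,
                median_a = stats::median(a), median_b = stats::median(b)))
  }
  p <- stats::wilcox.test(a, b, paired = TRUE,
                          exact = length(a) < 25)$p.value
  list(n_distances = length(a), p = p,
       median_a = stats::median(a), median_b = stats::median(b))
}

#' Median profile across replicate motif sets
#'
#' Applies a per-distance profiling function to each replicate set (e.g.
#' the pseudoESE replicates) and returns the per-distance median of the
#' class proportions with the mean site counts, the comparator used for the
#' composition-controlled contrasts.
#'
#' @param profiles list of profile data.frames sharing a `distance` column.
#' @return data.frame with per-distance median proportions and mean site
#'   counts.
#' @export
median_profile <- function(profiles) {
  d <- profiles[[1]]$distance
  med <- function(col) apply(vapply(profiles, function(p) p[[col]],
                                    numeric(length(d))), 1,
                             stats::median, na.rm = TRUE)
  mn <- function(col) rowMeans(vapply(profiles, function(p)
    as.numeric(p[[col]]), numeric(length(d))))
  out <- data.frame(distance = d)
  for (col in intersect(c("sites_ese", "subst_ese", "snp_ese",
                          "sites_non", "subst_non", "snp_non"),
                        names(profiles[[1]]))) out[[col]] <- mn(col)
  for (col in intersect(c("prop_ese", "prop_non"), names(profiles[[1]]))) {
    out[[col]] <- med(col)
  }
  out
}

#' Percent difference between two medians
#'
#' `100 * (median_ese - median_non) / median_non`, reported to 1 decimal
#' place, the summary used for divergence and SNP contrasts.
#'
#' @param median_ese,median_non the two medians; `median_non` must be
#'   nonzero.
#' @return percent difference, rounded to 1 d.p.
#' @examples
#' percent_difference(0.30, 0.36) # -16.7
#' @export
percent_difference <- function(median_ese, median_non) {
  if (median_non == 0) stop("zero denominator")
  round(100 * (median_ese - median_non) / median_non, 1)
}

#' SNP-bearing site proportions by distance from the exon boundary
#'
#' For each distance from the nearest exon junction and each ESE class
#' (by the mask of `set` on the exon sequence), the proportion of sites
#' carrying at least one SNP. Multiple SNPs at one position count once.
#'
#' @param exons an [exon_table()].
#' @param snps data.frame with columns `exon_id` and `offset` (0-based
#'   position within the exon).
#' @param set a [hexamer_set()].
#' @param max_distance distance cap in nt.
#' @return data.frame per distance: `distance`, `sites_ese`, `snp_ese`,
#'   `sites_non`, `snp_non`, `prop_ese`, `prop_non`.
#' @export
snp_profile <- function(exons, snps, set, max_distance = 100) {
  lens <- nchar(exons$exon_seq)
  snp_key <- unique(paste(snps$exon_id, snps$offset))
  if (nrow(snps) > 0) {
    bad <- snps$offset < 0 |
      snps$offset >= lens[match(snps$exon_id, exons$exon_id)]
    if (any(is.na(bad)) || any(bad, na.rm = TRUE)) {
      stop("SNP offset outside its exon (offsets are 0-based)")
    }
  }
  se <- pe <- sn <- pn <- integer(max_distance)
  for (i in seq_len(nrow(exons))) {
    L <- lens[i]
    mask <- mask_ese_positions(exons$exon_seq[i], set)
    pos <- seq_len(L)
    d <- pmin(pos, L - pos + 1L)
    keep <- d <= max_distance
    has_snp <- paste(exons$exon_id[i], pos - 1L) %in% snp_key
    for (j in pos[keep]) {
      if (mask[j]) {
        se[d[j]] <- se[d[j]] + 1L
        if (has_snp[j]) pe[d[j]] <- pe[d[j]] + 1L
      } else {
        sn[d[j]] <- sn[d[j]] + 1L
        if (has_snp[j]) pn[d[j]] <- pn[d[j]] + 1L
      }
    }
  }
  data.frame(distance = seq_len(max_distance),
             sites_ese = se, snp_ese = pe, sites_non = sn, snp_non = pn,
             prop_ese = ifelse(se > 0, pe / se, NA_real_),
             prop_non = ifelse(sn > 0, pn / sn, NA_real_))
}

#' Net impact of enhancer constraint on the synonymous substitution rate
#'
#' Two-stage whole-percent estimate: the local reduction near exon ends is
#' the in-ESE rate deficit times the ESE density near ends (e.g. a 15%
#' deficit at 30% density gives a 5% local reduction, round-half-up); the
#' net genome-wide reduction scales the local figure by the fraction of
#' sequence near exon ends (5% at 80% gives 4%).
#'
#' @param rate_deficit fractional rate deficit inside ESEs (e.g. 0.15).
#' @param ese_density_ends fraction of near-end sequence that is ESE.
#' @param fraction_near_ends fraction of exonic sequence near exon ends.
#' @return list with `local_percent` and `net_percent` (integers).
#' @examples
#' net_selection_estimate(0.15, 0.30, 0.80)
#' @export
net_selection_estimate <- function(rate_deficit, ese_density_ends,
                                   fraction_near_ends) {
  stopifnot(rate_deficit >= 0, rate_deficit <= 1,
            ese_density_ends >= 0, ese_density_ends <= 1,
            fraction_near_ends >= 0, fraction_near_ends <= 1)
  half_up <- function(x) floor(x + 0.5)
  local <- half_up(100 * rate_deficit * ese_density_ends)
  net <- half_up(local * fraction_near_ends)
  list(local_percent = local, net_percent = net)
}
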