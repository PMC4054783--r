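#' Frame codons fully specified by a hexamer
#'
#' A hexamer n1..n6 can sit in any reading frame; the codons specified
#' completely are the four overlapping triplets n1n2n3, n2n3n4, n3n4n5,
#' n4n5n6. Stop triplets are retained here and dropped at the counting
#' stage.
#'
#' @param hexamer a single 6-mer over ACGT.
#' @return character vector of four codons, in offset order.
#' @examples
#' extract_frame_codons("GAAGAA")
#' @export
extract_frame_codons <- function(hexamer) {
  hexamer <- toupper(hexamer)
  if (length(hexamer) != 1 || nchar(hexamer) != 6 ||
      grepl("[^ACGT]", hexamer)) {
    stop("input must be a single hexamer over ACGT")
  }
  substring(hexamer, 1:4, 3:6)
}

# internal: frame-codon counts over a vector of hexamers, stops dropped,
# returned as proportions over the 61 sense codons (in sense_codons() order)
.frame_codon_props <- function(hexamers, codons) {
  idx <- c(vapply(1:4, function(k)
    match(substr(hexamers, k, k + 2), codons), integer(length(hexamers))))
  cnt <- tabulate(idx[!is.na(idx)], nbins = length(codons))
  cnt / sum(cnt)
}

#' Read a codon usage table
#'
#' Two-column TSV (codon, relative frequency or per-thousand count) in the
#' codon-usage-database convention; stop codons are removed and the sense
#' frequencies renormalised to sum to 1.
#'
#' @param path file path; defaults to the bundled human reference usage.
#' @return named numeric vector over the 61 sense codons.
#' @export
read_codon_usage <- function(path = system.file("extdata",
                                                "human_codon_usage.tsv",
                                                package = "esetools")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  u <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  normalize_codon_usage(u)
}

#' @rdname read_codon_usage
#' @param usage named numeric vector codon -> weight (any scale); names must
#'   cover the sense codons.
#' @export
normalize_codon_usage <- function(usage) {
  cods <- sense_codons()
  miss <- setdiff(cods, names(usage))
  if (length(miss)) stop("usage table missing codon(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  u <- usage[cods]
  if (any(u < 0) || sum(u) <= 0) stop("usage weights must be non-negative")
  u / sum(u)
}

#' Hexamer preference index (HPI)
#'
#' Per-codon randomization Z score measuring how enriched each codon is in
#' the frame-codons of a motif catalogue, relative to codon-usage-weighted
#' random hexamers. Observed codon proportions are the frame-codon counts
#' of the set with stops removed and renormalised. The null generates
#' `reps` random catalogues of the same size, each random hexamer being the
#' concatenation of two sense codons drawn in proportion to `usage`, parsed
#' identically (frame codons, stops dropped). HPI_c = (obs_c - mean_c) /
#' sd_c.
#'
#' The null random draws are made as exactly two vectorised
#' usage-weighted `sample()` calls of `length(set) * reps` codons each
#' (first codons of all replicate hexamers, then second codons), so the
#' stream is reproducible from `seed`.
#'
#' @param set a non-empty [hexamer_set()].
#' @param usage named sense-codon frequencies (see
#'   [normalize_codon_usage()]).
#' @param reps number of random catalogues.
#' @param seed integer seed.
#' @return data.frame (one row per sense codon): `codon`, `aa`, `observed`,
#'   `null_mean`, `null_sd`, `hpi`. `hpi` is `NA` with a warning where the
#'   null sd is zero.
#' @export
hpi <- function(set, usage, reps = 10000, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (length(set) == 0) stop("empty motif set")
  cods <- sense_codons()
  u <- normalize_codon_usage(usage)
  obs <- .frame_codon_props(as.character(set), cods)
  n <- length(set)
  set.seed(seed)
  c1 <- sample(cods, n * reps, replace = TRUE, prob = u)
  c2 <- sample(cods, n * reps, replace = TRUE, prob = u)
  hex <- paste0(c1, c2)
  # per-replicate proportions
  idx <- c(vapply(1:4, function(k)
    match(substr(hex, k, k + 2), cods), integer(length(hex))))
  rep_id <- rep(rep(seq_len(reps), each = n), times = 4)
  keep <- !is.na(idx)
  flat <- (rep_id[keep] - 1L) * length(cods) + idx[keep]
  cnt <- tabulate(flat, nbins = reps * length(cods))
  props <- matrix(cnt, nrow = reps, ncol = length(cods), byrow = TRUE)
  props <- props / rowSums(props)
  mu <- colMeans(props)
  sdv <- apply(props, 2, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  if (any(sdv == 0)) {
    warning("null sd is zero for some codon(s); HPI reported as NA there")
  }
  data.frame(codon = cods, aa = unname(translate_codons(cods)),
             observed = obs, null_mean = mu, null_sd = sdv, hpi = as.numeric(z),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Codon usage-vs-distance regression slopes
#'
#' For each codon, the least-squares slope of its proportional usage on the
#' distance from the exon boundary. Distance is indexed in codons from the
#' nearest boundary within the exon half (each exon split at its midpoint),
#' capped at `max_distance` (default 35 codons, about 100 nt). Proportional
#' usage at a distance is the codon's count divided by its synonymous
#' family's count at that distance; distances where the family is absent
#' are skipped for that codon. A negative slope means the codon is
#' relatively preferred near exon boundaries.
#'
#' @param exons character vector of in-frame coding exon sequences, or an
#'   [exon_table()] whose `exon_seq` holds in-frame coding sequence.
#' @param max_distance distance cap in codons.
#' @param proportional if `FALSE`, absolute per-codon frequency at each
#'   distance is regressed instead of the within-family proportion.
#' @return data.frame: `codon`, `aa`, `slope`, `se`, `n_bins`.
#' @export
codon_slopes <- function(exons, max_distance = 35, proportional = TRUE) {
  seqs <- if (is.data.frame(exons)) exons$exon_seq else as.character(exons)
  seqs <- toupper(seqs)
  if (any(nchar(seqs) %% 3 != 0)) stop("exon sequences must be in frame")
  cods <- sense_codons()
  aa <- translate_codons(cods)
  # accumulate codon x distance counts
  counts <- matrix(0L, nrow = length(cods), ncol = max_distance,
                   dimnames = list(cods, NULL))
  for (s in seqs) {
    K <- nchar(s) %/% 3
    if (K == 0) next
    st <- 3L * seq_len(K) - 2L
    cc <- substring(s, st, st + 2L)
    d <- pmin(seq_len(K), K - seq_len(K) + 1L)
    ok <- d <= max_distance
    ci <- match(cc[ok], cods)
    dd <- d[ok]
    keep <- !is.na(ci)
    for (j in which(keep)) counts[ci[j], dd[j]] <- counts[ci[j], dd[j]] + 1L
  }
  fam_counts <- rowsum(counts, group = aa)
  res <- lapply(seq_along(cods), function(i) {
    fam <- fam_counts[aa[i], ]
    dsup <- which(fam > 0)
    y <- if (proportional) counts[i, dsup] / fam[dsup] else
      counts[i, dsup] / sum(counts)
    if (length(dsup) < 3) {
      return(data.frame(codon = cods[i], aa = aa[i], slope = NA_real_,
                        se = NA_real_, n_bins = length(dsup)))
    }
    fit <- stats::lm(y ~ dsup)
    co <- suppressWarnings(summary(fit))$coefficients  # constant y (single-codon families) is fine
    sl <- co["dsup", "Estimate"]
    se <- if (nrow(co) >= 2) co["dsup", "Std. Error"] else NA_real_
    data.frame(codon = cods[i], aa = aa[i], slope = sl, se = se,
               n_bins = length(dsup), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fisher's method for combining independent P values
#'
#' @param p numeric vector of P values in (0, 1].
#' @param df degrees of freedom for the reference chi-square distribution;
#'   defaults to `2 * length(p)`.
#' @return list with `chisq` (`-2 * sum(log(p))`) and `p`.
#' @export
fisher_method <- function(p, df = 2 * length(p)) {
  stopifnot(all(p > 0), all(p <= 1))
  x <- -2 * sum(log(p))
  list(chisq = x, p = stats::pchisq(x, df = df, lower.tail = FALSE))
}

#' Concordance between HPI and usage-distance slopes over synonymous pairs
#'
#' All synonymous codon pairs are oriented so the HPI difference is
#' positive; the sign of the slope difference (slope of the higher-HPI
#' codon minus slope of the lower) is then tallied. If a catalogue
#' captures true enhancers, codons preferred in it should also be preferred
#' near boundaries, giving an excess of negative slope differences and a
#' negative correlation of the slope difference with the HPI difference.
#' Reports a one-tailed exact binomial P for the excess of negatives (pairs
#' with a zero slope difference dropped), a one-tailed Spearman correlation
#' P (alternative: negative), and their Fisher combination.
#'
#' @param hpi_table output of [hpi()].
#' @param slope_table output of [codon_slopes()].
#' @param df degrees of freedom for the combined chi-square (default 4; a
#'   df = 2 compatibility value may be supplied).
#' @return list with `n_pairs`, `negatives`, `positives`, `p_binomial`,
#'   `rho`, `p_rho`, `chisq`, `p_overall`, and the oriented `pairs`
#'   data.frame (`codon_high`, `codon_low`, `d_hpi`, `d_slope`).
#' @export
pair_concordance <- function(hpi_table, slope_table, df = 4) {
  sp <- synonymous_pairs()
  h <- stats::setNames(hpi_table$hpi, hpi_table$codon)
  s <- stats::setNames(slope_table$slope, slope_table$codon)
  dh <- h[sp$codon1] - h[sp$codon2]
  hi <- ifelse(dh >= 0, sp$codon1, sp$codon2)
  lo <- ifelse(dh >= 0, sp$codon2, sp$codon1)
  d_hpi <- abs(dh)
  d_slope <- s[hi] - s[lo]
  drop <- is.na(d_hpi) | is.na(d_slope) | d_hpi == 0
  if (any(drop)) {
    message(sprintf("%d pair(s) dropped (undefined HPI/slope or HPI tie)",
                    sum(drop)))
  }
  d_hpi <- d_hpi[!drop]
  d_slope <- d_slope[!drop]
  hi <- hi[!drop]; lo <- lo[!drop]
  neg <- sum(d_slope < 0)
  pos <- sum(d_slope > 0)
  p_binom <- stats::pbinom(neg - 1, neg + pos, 0.5, lower.tail = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(d_hpi, d_slope, method = "spearman",
                    alternative = "less"))
  # numerically zero P values are floored so the log-combination is defined
  fm <- fisher_method(pmax(c(p_binom, ct$p.value), 1e-300), df = df)
  list(n_pairs = length(d_hpi), negatives = neg, positives = pos,
       p_binomial = p_binom, rho = unname(ct$estimate), p_rho = ct$p.value,
       chisq = fm$chisq, p_overall = fm$p,
       pairs = data.frame(codon_high = hi, codon_low = lo, d_hpi = d_hpi,
                          d_slope = d_slope, row.names = NULL,
                          stringsAsFactors = FALSE))
}
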