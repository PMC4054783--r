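# Synthetic-data generators: every analysis stage in the package can be
# exercised against data with known ground truth, download-free.
# All generators are deterministic given their seed; the returned `truth`
# element records exactly what was imposed.

#' Draw motif catalogues from a known true pool
#'
#' Draws a "true ESE pool" uniformly from the 4,096-hexamer universe, then
#' each catalogue without replacement from that pool — the generative model
#' behind the pool-sampling null and the pool-size estimator. With
#' `pool_size = 4096` this reduces to the uniform null.
#'
#' @param pool_size size of the true pool.
#' @param set_sizes integer vector of catalogue sizes (each `<= pool_size`).
#' @param seed integer seed.
#' @param universe character vector universe (default [all_hexamers()]).
#' @return list with `sets` (named list of [hexamer_set()]), `pool`
#'   (a [hexamer_set()]) and `truth` (pool size and seed).
#' @export
gen_hexamer_catalogues <- function(pool_size, set_sizes, seed,
                                   universe = all_hexamers()) {
  if (missing(seed)) stop("'seed' is required")
  if (any(set_sizes > pool_size)) stop("set size exceeds the pool")
  if (pool_size > length(universe)) stop("pool exceeds the universe")
  set.seed(seed)
  pool <- sample(universe, pool_size)
  sets <- lapply(seq_along(set_sizes), function(i) {
    hexamer_set(sample(pool, set_sizes[i]), name = sprintf("sim%d", i))
  })
  names(sets) <- vapply(sets, set_name, character(1))
  list(sets = sets, pool = hexamer_set(sort(pool), name = "pool"),
       truth = list(pool_size = pool_size, set_sizes = set_sizes,
                    seed = seed))
}

# logistic embedding curve: stamp probability at distance d from the
# nearest exon boundary (first exonic base = distance 1)
.embed_curve <- function(d, plateau, floor_, midpoint, scale) {
  floor_ + (plateau - floor_) / (1 + exp((d - midpoint) / scale))
}

# stamp motifs onto a character vector of bases; returns the modified bases
.stamp <- function(chars, starts, pool) {
  if (length(starts) == 0) return(chars)
  motifs <- sample(as.character(pool), length(starts), replace = TRUE)
  for (j in seq_along(starts)) {
    chars[starts[j]:(starts[j] + 5L)] <- strsplit(motifs[j], "")[[1]]
  }
  chars
}

#' Generate a synthetic exon set with known ESE structure
#'
#' Emulates the statistical structure the analyses assume: internal exons
#' (lognormal lengths, median about 130 nt — the typical human internal
#' exon) with 100-nt intron flanks; motifs from a supplied pool stamped
#' over background sequence at positions drawn from a logistic
#' boundary-decay curve (plateau near splice sites, floor in the core);
#' optional coding sequence built from a codon usage table with an optional
#' linear distance trend in one synonymous codon pair; splice-site scores
#' rank-correlated with realized flank ESE density through a Gaussian
#' copula; intron lengths optionally rank-correlated with flank density;
#' class labels with embedding multipliers. Stamps use overwrite semantics
#' and the truth mask is re-derived from the final sequence against the
#' pool, so truth equals what [mask_ese_positions()] finds.
#'
#' @param n_exons number of exons.
#' @param pool a [hexamer_set()] (or character vector): the true ESE pool.
#' @param seed integer seed.
#' @param exon_lens optional fixed exon lengths (recycled); otherwise drawn
#'   lognormal.
#' @param len_meanlog,len_sdlog,min_exon_len exon length distribution
#'   (defaults: median 130 nt, sdlog 0.35, minimum 60 nt).
#' @param intron_flank stored intron flank width (nt).
#' @param intron_meanlog,intron_sdlog flanking intron length distribution
#'   (defaults: median 1,500 nt, sdlog 1).
#' @param base_comp background base composition (named A, C, G, T).
#' @param embed_plateau,embed_floor,embed_midpoint,embed_scale logistic
#'   per-position stamp probabilities near the boundary and in the core
#'   (defaults give roughly 30% flank / 3% core nucleotide coverage) and
#'   the curve's midpoint (nt) and scale.
#' @param embed_introns if `TRUE`, intron flanks are stamped at
#'   `embed_floor`; by default introns carry chance matches only.
#' @param coding build exon sequence from codons (length rounded to a
#'   multiple of 3).
#' @param usage sense-codon usage for coding exons (default bundled human
#'   reference).
#' @param slope_pair optional list (`codon_up`, `codon_down`, `p0`,
#'   `beta`): within occurrences of the synonymous pair, the probability of
#'   `codon_up` at codon distance t from the boundary is `p0 + beta * t`
#'   (clipped to 0.02..0.98), imposing a linear usage-vs-distance trend.
#' @param score_rho target Spearman correlation between each end's splice
#'   score and its flank density (terminal 50 nt minus terminal 3);
#'   mapped to the Gaussian copula via `2 * sin(pi * rho / 6)`.
#' @param intron_rho target Spearman correlation between each end's
#'   final-100-nt flank density and its flanking intron length.
#' @param p_alternative,alternative_mult fraction of exons labelled
#'   alternative and the embedding multiplier applied to them.
#' @param p_conserved,conserved_mult likewise for the conserved label.
#' @return list with `exons` (an [exon_table()]), `masks` (per-exon logical
#'   truth masks), `pool`, and `truth` (all imposed parameters).
#' @export
gen_genome <- function(n_exons = 1000, pool, seed,
                       exon_lens = NULL,
                       len_meanlog = log(130), len_sdlog = 0.35,
                       min_exon_len = 60,
                       intron_flank = 100,
                       intron_meanlog = log(1500), intron_sdlog = 1,
                       base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       embed_plateau = 0.06, embed_floor = 0.005,
                       embed_midpoint = 50, embed_scale = 8,
                       embed_introns = FALSE,
                       coding = FALSE, usage = NULL,
                       slope_pair = NULL,
                       score_rho = 0, intron_rho = 0,
                       p_alternative = 0.3, alternative_mult = 1,
                       p_conserved = 0.7, conserved_mult = 1) {
  if (missing(seed)) stop("'seed' is required")
  if (missing(pool)) stop("a motif 'pool' is required")
  bases <- c("A", "C", "G", "T")
  comp <- base_comp[bases]
  stopifnot(!anyNA(comp), all(comp >= 0), sum(comp) > 0)
  comp <- comp / sum(comp)
  if (max(.embed_curve(1, embed_plateau, embed_floor, embed_midpoint,
                       embed_scale)) > 1) {
    stop("embedding curve demands stamp probability > 1")
  }
  set.seed(seed)
  if (is.null(exon_lens)) {
    exon_lens <- pmax(round(stats::rlnorm(n_exons, len_meanlog, len_sdlog)),
                      min_exon_len)
  } else {
    exon_lens <- rep_len(as.integer(exon_lens), n_exons)
  }
  if (coding) {
    exon_lens <- pmax(3L * round(exon_lens / 3), 3L)
    if (is.null(usage)) usage <- read_codon_usage()
    u <- normalize_codon_usage(usage)
    cods <- sense_codons()
  }
  alt <- stats::runif(n_exons) < p_alternative
  cons <- stats::runif(n_exons) < p_conserved
  mult <- ifelse(alt, alternative_mult, 1) * ifelse(cons, conserved_mult, 1)
  exon_seq <- up_seq <- down_seq <- character(n_exons)
  for (i in seq_len(n_exons)) {
    L <- exon_lens[i]
    if (coding) {
      K <- L %/% 3L
      ci <- sample(cods, K, replace = TRUE, prob = u)
      if (!is.null(slope_pair)) {
        t_cod <- pmin(seq_len(K), K - seq_len(K) + 1L)
        in_pair <- ci %in% c(slope_pair$codon_up, slope_pair$codon_down)
        p_up <- pmin(pmax(slope_pair$p0 + slope_pair$beta * t_cod,
                          0.02), 0.98)
        pick_up <- stats::runif(K) < p_up
        ci[in_pair] <- ifelse(pick_up[in_pair], slope_pair$codon_up,
                              slope_pair$codon_down)
      }
      chars <- strsplit(paste(ci, collapse = ""), "")[[1]]
    } else {
      chars <- sample(bases, L, replace = TRUE, prob = comp)
    }
    if (embed_plateau > 0 && L >= 6) {
      d <- pmin(seq_len(L - 5L), L - seq_len(L - 5L) - 4L)
      p <- pmin(.embed_curve(d, embed_plateau, embed_floor,
                             embed_midpoint, embed_scale) * mult[i], 1)
      starts <- which(stats::runif(L - 5L) < p)
      chars <- .stamp(chars, starts, pool)
    }
    exon_seq[i] <- paste(chars, collapse = "")
    mk_intron <- function() {
      ch <- sample(bases, intron_flank, replace = TRUE, prob = comp)
      if (embed_introns && intron_flank >= 6) {
        st <- which(stats::runif(intron_flank - 5L) < embed_floor)
        ch <- .stamp(ch, st, pool)
      }
      paste(ch, collapse = "")
    }
    up_seq[i] <- mk_intron()
    down_seq[i] <- mk_intron()
  }
  masks <- lapply(exon_seq, mask_ese_positions, set = pool)
  # flank densities actually realized, for the score / intron copulas
  dens_at <- function(i, idx) mean(masks[[i]][idx])
  d50m3_5 <- vapply(seq_len(n_exons), function(i)
    dens_at(i, seq.int(4L, min(50L, exon_lens[i]))), numeric(1))
  d50m3_3 <- vapply(seq_len(n_exons), function(i)
    dens_at(i, seq.int(max(1L, exon_lens[i] - 49L),
                       max(1L, exon_lens[i] - 3L))), numeric(1))
  d100_5 <- vapply(seq_len(n_exons), function(i)
    dens_at(i, seq_len(min(100L, exon_lens[i]))), numeric(1))
  d100_3 <- vapply(seq_len(n_exons), function(i)
    dens_at(i, seq.int(max(1L, exon_lens[i] - 99L), exon_lens[i])),
    numeric(1))
  copula <- function(dens, rho_s) {
    zr <- stats::qnorm(rank(dens, ties.method = "random") / (n_exons + 1))
    rp <- 2 * sin(pi * rho_s / 6)
    rp * zr + sqrt(1 - rp^2) * stats::rnorm(n_exons)
  }
  score5 <- copula(d50m3_5, score_rho)
  score3 <- copula(d50m3_3, score_rho)
  up_len <- pmax(round(stats::qlnorm(stats::pnorm(copula(d100_5, intron_rho)),
                                     intron_meanlog, intron_sdlog)),
                 intron_flank)
  down_len <- pmax(round(stats::qlnorm(stats::pnorm(copula(d100_3,
                                                           intron_rho)),
                                       intron_meanlog, intron_sdlog)),
                   intron_flank)
  exons <- exon_table(data.frame(
    exon_id = sprintf("ex%05d", seq_len(n_exons)),
    gene_id = sprintf("g%05d", seq_len(n_exons)),
    exon_seq = exon_seq, up_intron_seq = up_seq, down_intron_seq = down_seq,
    up_intron_len = up_len, down_intron_len = down_len,
    score5 = score5, score3 = score3,
    alternative = alt, conserved = cons, coding = coding,
    stringsAsFactors = FALSE))
  list(exons = exons, masks = masks,
       pool = if (inherits(pool, "hexamer_set")) pool else
         hexamer_set(pool, "pool"),
       truth = list(seed = seed, n_exons = n_exons, coding = coding,
                    embed_plateau = embed_plateau, embed_floor = embed_floor,
                    embed_midpoint = embed_midpoint,
                    embed_scale = embed_scale, score_rho = score_rho,
                    intron_rho = intron_rho, slope_pair = slope_pair,
                    p_alternative = p_alternative,
                    alternative_mult = alternative_mult,
                    p_conserved = p_conserved,
                    conserved_mult = conserved_mult,
                    base_comp = as.list(comp)))
}

#' Generate orthologous exon pairs with an in-ESE rate deficit
#'
#' Creates the second-species copy of each coding exon by substituting each
#' analysable four-fold degenerate third position with probability `d`
#' outside the truth ESE mask and `d * r` inside (substitution to a
#' uniformly chosen different base, which preserves the four-fold family);
#' all other positions are copied unchanged. A multiplier r below 1 imposes
#' slower ESE evolution.
#'
#' @param genome output of [gen_genome()] with `coding = TRUE`.
#' @param d substitution probability at four-fold sites outside ESEs.
#' @param r in-ESE rate multiplier (`d * max(1, r) <= 1`).
#' @param seed integer seed.
#' @return list with `pairs` (data.frame: `gene_id`, `exon_id`, `seq1`,
#'   `seq2`) and `truth` (`d`, `r`, per-exon substituted positions).
#' @export
gen_ortholog_pairs <- function(genome, d, r, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (d < 0 || d * max(1, r) > 1 || r < 0) stop("invalid rates")
  if (!isTRUE(genome$truth$coding)) {
    stop("ortholog pairs require a coding genome (gen_genome(coding = TRUE))")
  }
  set.seed(seed)
  exons <- genome$exons
  bases <- c("A", "C", "G", "T")
  n <- nrow(exons)
  seq2 <- character(n)
  subs <- vector("list", n)
  for (i in seq_len(n)) {
    s1 <- exons$exon_seq[i]
    chars <- strsplit(s1, "")[[1]]
    ff <- fourfold_sites(list(seq1 = s1, seq2 = s1))
    if (length(ff)) {
      pr <- ifelse(genome$masks[[i]][ff], d * r, d)
      hit <- ff[stats::runif(length(ff)) < pr]
      for (p in hit) chars[p] <- sample(setdiff(bases, chars[p]), 1)
      subs[[i]] <- hit
    } else subs[[i]] <- integer(0)
    seq2[i] <- paste(chars, collapse = "")
  }
  list(pairs = data.frame(gene_id = exons$gene_id, exon_id = exons$exon_id,
                          seq1 = exons$exon_seq, seq2 = seq2,
                          stringsAsFactors = FALSE),
       truth = list(d = d, r = r, seed = seed, substituted = subs))
}

#' Generate SNPs with an in-ESE density deficit
#'
#' Each exonic site carries a SNP with probability `s` outside the truth
#' ESE mask and `s * q` inside; `q < 1` imposes the purifying-selection
#' deficit.
#'
#' @param genome output of [gen_genome()].
#' @param s per-site SNP probability outside ESEs.
#' @param q in-ESE multiplier (`s * max(1, q) <= 1`).
#' @param seed integer seed.
#' @return list with `snps` (data.frame: `exon_id`, `offset` 0-based) and
#'   `truth`.
#' @export
gen_snps <- function(genome, s, q, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (s < 0 || s * max(1, q) > 1 || q < 0) stop("invalid rates")
  set.seed(seed)
  exons <- genome$exons
  out <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    m <- genome$masks[[i]]
    pr <- ifelse(m, s * q, s)
    hit <- which(stats::runif(length(m)) < pr)
    if (length(hit)) {
      out[[i]] <- data.frame(exon_id = exons$exon_id[i], offset = hit - 1L,
                             stringsAsFactors = FALSE)
    }
  }
  snps <- if (any(!vapply(out, is.null, logical(1)))) {
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  } else data.frame(exon_id = character(0), offset = integer(0))
  list(snps = snps, truth = list(s = s, q = q, seed = seed))
}
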