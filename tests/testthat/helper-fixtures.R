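# Shared fixture builders and independent oracles. All fixtures are built
# in code; nothing is read from disk except the bundled usage table.

# a reproducible random motif pool
fix_pool <- function(n, seed) {
  set.seed(seed)
  hexamer_set(sample(all_hexamers(), n), name = sprintf("pool%d", n))
}

# random CDS of n_codons starting ATG and ending TAA, no internal stops
fix_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# minimal exon table: bare exon sequences with intron flanks of all-N-free
# random background
fix_exons <- function(seqs, up = NULL, down = NULL) {
  n <- length(seqs)
  rand_intron <- function() paste(sample(c("A", "C", "G", "T"), 100,
                                         replace = TRUE), collapse = "")
  exon_table(data.frame(
    exon_id = sprintf("e%03d", seq_len(n)),
    exon_seq = seqs,
    up_intron_seq = if (is.null(up)) replicate(n, rand_intron()) else up,
    down_intron_seq = if (is.null(down)) replicate(n, rand_intron()) else
      down,
    stringsAsFactors = FALSE))
}

# independent brute-force occurrence counter for octamer-derived hexamers
oracle_octamer_hexamers <- function(octamers, min_occ) {
  counts <- list()
  for (oc in octamers) {
    for (off in 1:3) {
      h <- substr(oc, off, off + 5)
      counts[[h]] <- (counts[[h]] %||% 0) + 1
    }
  }
  sort(names(counts)[unlist(counts) >= min_occ])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force HPI: loops over hexamers and replicates, sharing
# only the documented null RNG stream (two usage-weighted sample calls)
oracle_hpi <- function(set, usage, reps, seed) {
  cods <- sense_codons()
  u <- usage[cods] / sum(usage[cods])
  count_props <- function(hexes) {
    cnt <- stats::setNames(numeric(length(cods)), cods)
    for (h in hexes) {
      for (off in 1:4) {
        cod <- substr(h, off, off + 2)
        if (cod %in% cods) cnt[cod] <- cnt[cod] + 1
      }
    }
    cnt / sum(cnt)
  }
  obs <- count_props(as.character(set))
  n <- length(set)
  set.seed(seed)
  c1 <- sample(cods, n * reps, replace = TRUE, prob = u)
  c2 <- sample(cods, n * reps, replace = TRUE, prob = u)
  props <- matrix(NA_real_, reps, length(cods))
  for (r in seq_len(reps)) {
    idx <- ((r - 1) * n + 1):(r * n)
    props[r, ] <- count_props(paste0(c1[idx], c2[idx]))
  }
  mu <- colMeans(props)
  sdv <- apply(props, 2, stats::sd)
  (obs - mu) / sdv
}

# hand-made per-distance profile for paired tests
fix_profile <- function(prop_ese, prop_non, sites = 1000) {
  n <- length(prop_ese)
  data.frame(distance = seq_len(n),
             sites_ese = rep(sites, n),
             subst_ese = round(prop_ese * sites),
             sites_non = rep(sites, n),
             subst_non = round(prop_non * sites),
             prop_ese = prop_ese, prop_non = prop_non)
}
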