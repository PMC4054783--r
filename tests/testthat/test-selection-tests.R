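test_that("divergence profiling recovers imposed rate structure", {
  pool <- fix_pool(50, 51)
  g <- gen_genome(n_exons = 800, pool = pool, seed = 52, coding = TRUE)
  # identical sequences: zero divergence everywhere
  same <- gen_ortholog_pairs(g, d = 0, r = 1, seed = 53)
  p0 <- divergence_by_distance(same$pairs, pool)
  expect_true(all(p0$subst_ese == 0 & p0$subst_non == 0))
  # imposed deficit r = 0.85 at d = 0.35
  op <- gen_ortholog_pairs(g, d = 0.35, r = 0.85, seed = 54)
  prof <- divergence_by_distance(op$pairs, pool)
  tst <- paired_distance_test(prof, prof, cols = c("prop_ese", "prop_non"))
  expect_lt(tst$p, 0.01)
  pd <- percent_difference(tst$median_a, tst$median_b)
  expect_lt(abs(pd - (-15)), 8)
  # ESE and non-ESE site counts partition the analysable sites
  expect_true(all(prof$subst_ese <= prof$sites_ese))
  expect_true(all(prof$subst_non <= prof$sites_non))
  expect_warning(divergence_by_distance(
    data.frame(seq1 = "TTT", seq2 = "TTT"), pool), "no analysable")
})

test_that("percent difference follows the stated formula", {
  expect_equal(percent_difference(0.30, 0.36), -16.7)
  expect_equal(percent_difference(0.38, 0.34), 11.8)
  expect_equal(percent_difference(0.5, 0.5), 0)
  expect_error(percent_difference(0.1, 0), "zero")
})

test_that("pseudoESE sets honour the composition-matching contract", {
  one <- pseudo_ese_sets(c(A = 1, C = 0, G = 0, T = 0), size = 1,
                         replicates = 5, seed = 61)
  expect_true(all(vapply(one, function(s) identical(as.character(s),
                                                    "AAAAAA"), logical(1))))
  expect_error(pseudo_ese_sets(c(A = 1, C = 0, G = 0, T = 0), size = 2,
                               replicates = 1, seed = 1), "distinct")
  # uniform target: pooled base fractions within 3 Monte Carlo SE of 0.25
  unif <- pseudo_ese_sets(c(A = .25, C = .25, G = .25, T = .25), size = 100,
                          replicates = 100, seed = 62)
  pooled <- base_composition(
    hexamer_set(unique(unlist(lapply(unif, as.character)))))
  n_slots <- pooled$n_bases
  se <- sqrt(0.25 * 0.75 / n_slots)
  expect_true(all(abs(pooled$fractions - 0.25) < 4 * se))
  # matching an input catalogue's composition on average
  target <- base_composition(fix_pool(80, 63))$fractions
  reps <- pseudo_ese_sets(target, size = 80, replicates = 50, seed = 64)
  mean_comp <- rowMeans(vapply(reps, function(s)
    base_composition(s)$fractions, numeric(4)))
  expect_true(all(abs(mean_comp - target) < 0.03))
  # replicate sets have unique members of the right size
  expect_true(all(vapply(reps, function(s)
    length(s) == 80 && !anyDuplicated(s), logical(1))))
})

test_that("paired distance test behaves at its limits", {
  p <- fix_profile(rep(0.3, 10), rep(0.3, 10))
  expect_equal(paired_distance_test(p, p,
                                    cols = c("prop_ese", "prop_ese"))$p, 1)
  # one-sided shift at every distance: minimal attainable exact two-sided P
  p2 <- fix_profile(rep(0.3, 10) + seq(0.01, 0.1, by = 0.01), rep(0.3, 10))
  res <- paired_distance_test(p, p2, cols = c("prop_ese", "prop_ese"))
  expect_equal(res$p, 2 / 2^10)
  # small shared support warns
  p3 <- fix_profile(c(0.30, 0.31, 0.32, 0.33), c(0.36, 0.34, 0.39, 0.35))
  expect_warning(paired_distance_test(p3, p3,
                                      cols = c("prop_ese", "prop_non")),
                 "fewer than 6")
  # sparse cells are dropped by the site guard
  p4 <- fix_profile(rep(0.3, 10), rep(0.4, 10), sites = 10)
  expect_equal(suppressWarnings(paired_distance_test(p4, p4))$n_distances, 0)
})

test_that("SNP profiling deduplicates sites and recovers imposed deficits", {
  pool <- fix_pool(50, 71)
  ex <- fix_exons(paste(rep("A", 60), collapse = ""))
  snps <- data.frame(exon_id = c("e001", "e001"), offset = c(5, 5))
  sp <- snp_profile(ex, snps, hexamer_set("CCCCCC"))
  expect_equal(sum(sp$snp_non), 1) # two records, one site
  expect_true(all(snp_profile(ex, snps[0, ], hexamer_set("CCCCCC"))$snp_non
                  == 0))
  expect_error(snp_profile(ex, data.frame(exon_id = "e001", offset = 60),
                           pool), "outside")
  g <- gen_genome(n_exons = 1200, pool = pool, seed = 72)
  sn <- gen_snps(g, s = 0.036, q = 0.833, seed = 73)
  prof <- snp_profile(g$exons, sn$snps, pool)
  p_ese <- sum(prof$snp_ese) / sum(prof$sites_ese)
  p_non <- sum(prof$snp_non) / sum(prof$sites_non)
  se_e <- sqrt(0.03 * 0.97 / sum(prof$sites_ese))
  se_n <- sqrt(0.036 * 0.964 / sum(prof$sites_non))
  expect_lt(abs(p_ese - 0.036 * 0.833), 4 * se_e)
  expect_lt(abs(p_non - 0.036), 4 * se_n)
  # site classification equals the truth mask tally
  expect_equal(prof$sites_ese[1],
               sum(vapply(seq_len(nrow(g$exons)), function(i) {
                 m <- g$masks[[i]]
                 L <- length(m)
                 d <- pmin(seq_len(L), L - seq_len(L) + 1L)
                 sum(m[d == 1])
               }, numeric(1))))
})

test_that("median profile and the net-selection arithmetic are exact", {
  profs <- list(fix_profile(c(0.1, 0.2), c(0.3, 0.4)),
                fix_profile(c(0.3, 0.4), c(0.1, 0.2)),
                fix_profile(c(0.2, 0.3), c(0.2, 0.3)))
  mp <- median_profile(profs)
  expect_equal(mp$prop_ese, c(0.2, 0.3))
  expect_equal(mp$prop_non, c(0.2, 0.3))
  est <- net_selection_estimate(0.15, 0.30, 0.80)
  expect_equal(est$local_percent, 5)
  expect_equal(est$net_percent, 4)
  expect_equal(net_selection_estimate(0, 0.5, 0.5)$net_percent, 0)
  expect_equal(net_selection_estimate(0.33, 1, 1)$net_percent, 33)
})
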