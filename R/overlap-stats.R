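#' Expected pairwise overlap of two uniform random catalogues
#'
#' Mean of the hypergeometric overlap of two sets of sizes `n1` and `n2`
#' drawn independently without replacement from a universe of `N` motifs:
#' `n1 * n2 / N`.
#'
#' @param n1,n2 catalogue sizes.
#' @param N universe size (4,096 for the hexamer universe).
#' @return expected intersection size (numeric).
#' @examples
#' expected_pairwise_overlap(238, 238, 4096) # 13.8
#' @export
expected_pairwise_overlap <- function(n1, n2, N) {
  if (N <= 0) stop("'N' must be positive")
  stopifnot(n1 <= N, n2 <= N, n1 >= 0, n2 >= 0)
  n1 * n2 / N
}

#' Expected k-way intersection of uniform random catalogues
#'
#' For k independent draws without replacement of sizes `sizes` from a pool
#' of `N`, each motif is in sample i with probability `n_i / N`
#' independently across samples, so the expected k-way intersection is
#' `N * prod(sizes / N)` exactly.
#'
#' @param sizes integer vector of catalogue sizes.
#' @param N pool size.
#' @return expected intersection size (numeric).
#' @examples
#' expected_multiway_overlap(c(238, 238, 285), 400) # about 100
#' @export
expected_multiway_overlap <- function(sizes, N) {
  if (N <= 0) stop("'N' must be positive")
  if (any(sizes > N)) stop("every size must be <= N")
  N * prod(sizes / N)
}

#' Hypergeometric variance of a pairwise overlap
#'
#' Closed-form variance of the intersection of two uniform draws without
#' replacement, used as the analytic oracle for the simulated null.
#'
#' @inheritParams expected_pairwise_overlap
#' @return variance of the overlap count.
#' @export
pairwise_overlap_variance <- function(n1, n2, N) {
  m <- expected_pairwise_overlap(n1, n2, N)
  m * ((N - n1) / N) * ((N - n2) / (N - 1))
}

#' Simulate catalogue overlap under a sampling null
#'
#' Draws `reps` replicate families of catalogues of the given sizes, each
#' catalogue sampled without replacement from the null pool, and records the
#' k-way intersection size per replicate. The null pool is the uniform
#' hexamer universe (`universe`, default 4,096) unless `pool` is given, in
#' which case sampling is from that pool (a nominated-hexamer or
#' hypothesised true-ESE pool null).
#'
#' @param sizes integer vector of catalogue sizes (length >= 2 for a
#'   pairwise null, more for a multi-way null).
#' @param observed observed intersection count, or `NULL` to report the null
#'   distribution only.
#' @param universe uniform universe size.
#' @param pool optional pool: either an integer pool size or a
#'   [hexamer_set()] / character vector whose length defines the pool.
#' @param reps number of Monte Carlo replicates.
#' @param seed integer seed (mandatory: all randomness is seeded).
#' @return An object of class `"overlap_result"`: a list with `observed`,
#'   `expected_mean`, `expected_sd`, `fold`, `z`, `p` (empirical one-tailed
#'   fraction of replicates `>= observed`), `p_label` (reported as
#'   `"<1/reps"` when no replicate reaches the observed count), `reps`,
#'   `sizes`, `N`, and the replicate intersection counts `draws`.
#' @export
simulate_overlap <- function(sizes, observed = NULL, universe = 4096,
                             pool = NULL, reps = 10000, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(reps >= 1, length(sizes) >= 1)
  N <- if (is.null(pool)) universe else if (is.numeric(pool)) as.integer(pool)
       else length(pool)
  if (any(sizes > N)) stop("sample size exceeds the null pool")
  if (!is.null(observed) && observed < 0) stop("'observed' must be >= 0")
  set.seed(seed)
  k <- length(sizes)
  draws <- integer(reps)
  cnt <- integer(N)
  for (i in seq_len(reps)) {
    cnt[] <- 0L
    for (s in sizes) {
      idx <- sample.int(N, s)
      cnt[idx] <- cnt[idx] + 1L
    }
    draws[i] <- sum(cnt == k)
  }
  m <- mean(draws)
  sdv <- stats::sd(draws)
  out <- list(sizes = sizes, N = N, reps = reps, observed = observed,
              expected_mean = m, expected_sd = sdv, draws = draws)
  if (!is.null(observed)) {
    out$fold <- if (m > 0) observed / m else NA_real_
    out$z <- if (sdv > 0) (observed - m) / sdv else NA_real_
    exceed <- sum(draws >= observed)
    out$p <- exceed / reps
    out$p_label <- if (exceed == 0) sprintf("<%g", 1 / reps) else
      format(exceed / reps)
  }
  class(out) <- "overlap_result"
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap null: sizes [%s] from pool %d, %d reps>\n",
              paste(x$sizes, collapse = ", "), x$N, x$reps))
  cat(sprintf("  E = %.3f  sd = %.3f\n", x$expected_mean, x$expected_sd))
  if (!is.null(x$observed)) {
    cat(sprintf("  O = %d  F = %.2f  Z = %.2f  P = %s\n",
                x$observed, x$fold, x$z, x$p_label))
  }
  invisible(x)
}

#' Pairwise concordance table for a family of catalogues
#'
#' For every pair of catalogues, the observed intersection O, the analytic
#' uniform-null expectation E, fold enrichment F = O/E, and simulated Z and
#' empirical one-tailed P. The output mirrors the classic
#' n1/n2/O/E/F/Z/P concordance-table layout.
#'
#' @param sets named list of [hexamer_set()] objects.
#' @param universe uniform universe size (default 4,096).
#' @param reps Monte Carlo replicates per pair.
#' @param seed integer seed.
#' @param bonferroni logical; add a significance flag Bonferroni-adjusted
#'   over the number of pairs tested.
#' @param alpha family-wise significance level for the flag.
#' @return data.frame with columns set1, set2, n1, n2, O, E, F, Z, P,
#'   P_label (and `significant` if `bonferroni`).
#' @export
overlap_table <- function(sets, universe = 4096, reps = 10000, seed,
                          bonferroni = TRUE, alpha = 0.05) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(length(sets) >= 2)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  pairs <- utils::combn(seq_along(sets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    o <- length(intersect(toupper(sets[[i1]]), toupper(sets[[i2]])))
    sim <- simulate_overlap(c(length(sets[[i1]]), length(sets[[i2]])),
                            observed = o, universe = universe,
                            reps = reps, seed = seed + j)
    e <- expected_pairwise_overlap(length(sets[[i1]]), length(sets[[i2]]),
                                   universe)
    data.frame(set1 = nm[i1], set2 = nm[i2],
               n1 = length(sets[[i1]]), n2 = length(sets[[i2]]),
               O = o, E = e, F = o / e, Z = sim$z, P = sim$p,
               P_label = sim$p_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$significant <- out$P < alpha / nrow(out)
  out
}

#' Estimate the size of the underlying true-motif pool
#'
#' Assuming all catalogues are random samples (without replacement) from one
#' pool of true motifs, finds the pool size N whose expected k-way
#' intersection matches the observed/target intersection. Initialised at the
#' analytic solution `(prod(sizes) / target)^(1/(k-1))` and refined by
#' bisection on integer N with the expected intersection estimated by
#' simulation (`method = "simulation"`), or returned directly from the
#' closed form (`method = "analytic"`).
#'
#' @param sizes catalogue sizes.
#' @param target target (observed) intersection count; must not exceed the
#'   smallest catalogue.
#' @param reps simulation replicates per candidate pool size.
#' @param seed integer seed.
#' @param method `"simulation"` (default) or `"analytic"`.
#' @param round_to report the estimate rounded to this nearest multiple
#'   (default 10, matching "around 850"-style reporting); use 1 for the raw
#'   integer.
#' @return estimated pool size (numeric).
#' @export
estimate_pool_size <- function(sizes, target, reps = 10000, seed,
                               method = c("simulation", "analytic"),
                               round_to = 10) {
  method <- match.arg(method)
  stopifnot(length(sizes) >= 2, target >= 1)
  if (target > min(sizes)) {
    stop("target intersection larger than the smallest catalogue is impossible")
  }
  k <- length(sizes)
  n_analytic <- (prod(sizes) / target)^(1 / (k - 1))
  n_analytic <- max(n_analytic, max(sizes))
  if (method == "analytic") {
    return(round_to * round(n_analytic / round_to))
  }
  if (missing(seed)) stop("'seed' is required for simulation")
  sim_mean <- function(N, s) {
    simulate_overlap(sizes, universe = N, reps = reps,
                     seed = s)$expected_mean
  }
  lo <- max(sizes)
  hi <- max(ceiling(2 * n_analytic), lo + 1L)
  # expected intersection is strictly decreasing in N; widen until bracketed
  it <- 0L
  while (sim_mean(hi, seed + it) > target && it < 12L) {
    hi <- hi * 2L
    it <- it + 1L
  }
  lo_val <- sim_mean(lo, seed + 100L)
  if (lo_val < target) return(round_to * round(lo / round_to))
  step <- 0L
  while (hi - lo > max(2L, round_to %/% 2L)) {
    mid <- (lo + hi) %/% 2L
    if (sim_mean(mid, seed + 200L + step) >= target) lo <- mid else hi <- mid
    step <- step + 1L
  }
  round_to * round(((lo + hi) / 2) / round_to)
}

#' Per-catalogue contribution to an intersect set
#'
#' For each input catalogue, the Z score comparing its observed number of
#' members inside the `>= k`-way intersection against a simulated null in
#' which same-size catalogues are drawn uniformly from the hexamer universe.
#'
#' @param sets named list of [hexamer_set()] objects.
#' @param k intersection order (members in at least `k` catalogues).
#' @param reps Monte Carlo replicates.
#' @param seed integer seed.
#' @param universe uniform universe size.
#' @return data.frame with set, n, observed, expected_mean, expected_sd, Z.
#'   Z is `NA` with a warning where the null sd is 0.
#' @export
contribution_zscores <- function(sets, k, reps = 10000, seed,
                                 universe = 4096) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(length(sets) >= k, k >= 1)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  sizes <- lengths(sets)
  inter <- intersect_at_least(sets, k)
  observed <- vapply(sets, function(s) sum(toupper(s) %in% inter),
                     integer(1))
  set.seed(seed)
  nsets <- length(sets)
  sims <- matrix(0L, nrow = reps, ncol = nsets)
  cnt <- integer(universe)
  idxs <- vector("list", nsets)
  for (r in seq_len(reps)) {
    cnt[] <- 0L
    for (j in seq_len(nsets)) {
      idxs[[j]] <- sample.int(universe, sizes[j])
      cnt[idxs[[j]]] <- cnt[idxs[[j]]] + 1L
    }
    in_int <- cnt >= k
    for (j in seq_len(nsets)) sims[r, j] <- sum(in_int[idxs[[j]]])
  }
  mu <- colMeans(sims)
  sdv <- apply(sims, 2, stats::sd)
  z <- ifelse(sdv > 0, (observed - mu) / sdv, NA_real_)
  if (any(sdv == 0)) warning("degenerate null sd; Z undefined for some sets")
  data.frame(set = nm, n = as.integer(sizes), observed = observed,
             expected_mean = mu, expected_sd = sdv, Z = z,
             row.names = NULL, stringsAsFactors = FALSE)
}
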