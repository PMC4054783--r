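# Association of flank ESE density with splice-site strength, intron
# length, exon class and expression covariates.

#' Per-exon covariates for association tests
#'
#' Computes, per exon and end, the flank ESE densities used by the
#' association analyses: `dens5` / `dens3` over the terminal 50 nt omitting
#' the terminal 3 nt (the splice-strength analysis convention) and
#' `dens100_5` / `dens100_3` over the final 100 nt (the class and
#' intron-length analyses; no terminal exclusion). Scores, intron lengths,
#' exon length and class labels are carried through from the exon table.
#'
#' @param exons an [exon_table()].
#' @param set a [hexamer_set()].
#' @return data.frame with one row per exon.
#' @export
exon_covariates <- function(exons, set) {
  n <- nrow(exons)
  dens5 <- dens3 <- d100_5 <- d100_3 <- numeric(n)
  lens <- nchar(exons$exon_seq)
  for (i in seq_len(n)) {
    L <- lens[i]
    m <- mask_ese_positions(exons$exon_seq[i], set)
    w5 <- seq.int(4L, min(50L, L))            # terminal 50 minus terminal 3
    w3 <- seq.int(max(1L, L - 49L), max(1L, L - 3L))
    dens5[i] <- if (length(w5)) mean(m[w5]) else NA_real_
    dens3[i] <- if (length(w3)) mean(m[w3]) else NA_real_
    d100_5[i] <- mean(m[seq_len(min(100L, L))])
    d100_3[i] <- mean(m[seq.int(max(1L, L - 99L), L)])
  }
  out <- data.frame(exon_id = exons$exon_id, exon_len = lens,
                    dens5 = dens5, dens3 = dens3,
                    dens100_5 = d100_5, dens100_3 = d100_3,
                    stringsAsFactors = FALSE)
  for (col in c("gene_id", "score5", "score3", "up_intron_len",
                "down_intron_len", "alternative", "conserved")) {
    if (col %in% names(exons)) out[[col]] <- exons[[col]]
  }
  out
}

#' Splice-site strength vs flank ESE density
#'
#' Spearman correlation of the splice score at one exon end with the ESE
#' density of the adjacent flank (terminal 50 nt minus terminal 3 nt). A
#' negative correlation means weak splice sites carry denser enhancer
#' flanks.
#'
#' @param cov output of [exon_covariates()] (needs `score5`/`score3`).
#' @param end `5` or `3`.
#' @param min_exons minimum complete cases.
#' @return list with `rho`, `p`, `n`.
#' @export
strength_density_correlation <- function(cov, end = 5, min_exons = 10) {
  end <- as.character(end)
  score <- cov[[paste0("score", end)]]
  dens <- cov[[paste0("dens", end)]]
  ok <- stats::complete.cases(score, dens)
  if (sum(ok) < min_exons) stop("fewer than ", min_exons, " complete cases")
  if (stats::sd(score[ok]) == 0 || stats::sd(dens[ok]) == 0) {
    warning("constant score or density; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(score[ok], dens[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Flank ESE density between exon classes
#'
#' Mann-Whitney comparisons of the final-100-nt flank density between
#' alternative and constitutive exons, or between conserved and
#' non-conserved exons; two-tailed plus both one-tailed P values per end,
#' matching the class-comparison table layout.
#'
#' @param cov output of [exon_covariates()] with the relevant logical label
#'   column (`alternative` or `conserved`).
#' @param label `"alternative"` (TRUE class vs constitutive) or
#'   `"conserved"` (TRUE class vs non-conserved).
#' @return data.frame with one row per end: `end`, `n_class`, `n_other`,
#'   `p_two_tailed`, `p_greater` (class > other), `p_less`.
#' @export
class_comparison <- function(cov, label = c("alternative", "conserved")) {
  label <- match.arg(label)
  cls <- cov[[label]]
  if (is.null(cls)) stop("covariate table lacks a '", label, "' column")
  rows <- lapply(c("5", "3"), function(end) {
    d <- cov[[paste0("dens100_", end)]]
    a <- d[cls %in% TRUE]
    b <- d[cls %in% FALSE]
    if (length(a) == 0 || length(b) == 0) stop("a class is empty")
    if (length(a) < 5 || length(b) < 5) {
      warning("a class has fewer than 5 exons")
    }
    w <- function(alt) suppressWarnings(
      stats::wilcox.test(a, b, alternative = alt)$p.value)
    data.frame(end = end, n_class = length(a), n_other = length(b),
               p_two_tailed = w("two.sided"), p_greater = w("greater"),
               p_less = w("less"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flank ESE density vs flanking intron length
#'
#' Each exon end is paired with its own flanking intron (5' flank density
#' with the upstream intron, 3' with the downstream), both ends pooled;
#' per-end results are also returned. Optionally restricted to introns
#' shorter than `max_intron` (the classic analysis uses a 1,501 nt cut).
#'
#' @param cov output of [exon_covariates()] with intron length columns.
#' @param max_intron restrict to flanking introns strictly shorter than
#'   this, or `NULL` for all exons.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r`, `p`, `n` (pooled) and `per_end` data.frame.
#' @export
intron_length_correlation <- function(cov, max_intron = NULL,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  dens <- c(cov$dens100_5, cov$dens100_3)
  len <- c(cov$up_intron_len, cov$down_intron_len)
  end <- rep(c("5", "3"), each = nrow(cov))
  ok <- stats::complete.cases(dens, len)
  if (!is.null(max_intron)) ok <- ok & len < max_intron
  if (sum(ok) == 0) stop("no exon end passes the intron length filter")
  run <- function(sel) {
    ct <- suppressWarnings(stats::cor.test(dens[sel], len[sel],
                                           method = method))
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(sel))
  }
  pooled <- run(ok)
  per_end <- do.call(rbind, lapply(c("5", "3"), function(e) {
    as.data.frame(t(run(ok & end == e)))
  }))
  per_end$end <- c("5", "3")
  list(r = unname(pooled["r"]), p = unname(pooled["p"]),
       n = as.integer(pooled["n"]), per_end = per_end)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, then correlates the residuals of
#' least-squares fits of response and predictor on the covariate ranks.
#' With no covariates this reduces to the plain Spearman correlation.
#' P value from the t reference with `n - 2 - k` degrees of freedom.
#'
#' @param response,predictor numeric vectors.
#' @param covariates optional data.frame / matrix of numeric covariates.
#' @return list with `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(response, predictor, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = length(response), ncol = 0)
  }
  covariates <- as.matrix(covariates)
  ok <- stats::complete.cases(response, predictor, covariates)
  n <- sum(ok)
  k <- ncol(covariates)
  if (n < k + 10) stop("need at least covariates + 10 complete cases")
  r_resp <- rank(response[ok])
  r_pred <- rank(predictor[ok])
  if (k > 0) {
    rc <- apply(covariates[ok, , drop = FALSE], 2, rank)
    cc <- suppressWarnings(stats::cor(rc))
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-12, na.rm = TRUE)) {
      bad <- which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)[1, ]
      nms <- colnames(rc)
      if (is.null(nms)) nms <- paste0("V", seq_len(k))
      stop("collinear covariates: ", nms[bad[1]], " and ", nms[bad[2]])
    }
    r_resp <- stats::resid(stats::lm(r_resp ~ rc))
    r_pred <- stats::resid(stats::lm(r_pred ~ rc))
  }
  # residuals that are pure numerical noise (e.g. predictor among the
  # covariates) count as exactly zero
  if (stats::sd(r_pred) < 1e-6 || stats::sd(r_resp) < 1e-6) {
    return(list(rho = 0, p = 1, n = n, df = n - 2 - k))
  }
  rho <- stats::cor(r_resp, r_pred)
  df <- n - 2 - k
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = df), n = n, df = df)
}

#' Masked, normalised expression summaries
#'
#' Applies the negative-control mask (values below the per-tissue mean of
#' the negative controls are set to 0), drops genes that are zero in every
#' tissue after masking, normalises each tissue by its total signal, and
#' summarises each gene: expression breadth (fraction of tissues with a
#' nonzero value), tau (expression specificity,
#' `sum(1 - x_i / max(x)) / (n - 1)`; 0 = uniform, 1 = single-tissue),
#' mean and median over tissues.
#'
#' @param mat non-negative numeric matrix, genes x tissues.
#' @param control_means numeric vector of per-tissue negative-control mean
#'   expression (recycled names must match columns).
#' @return data.frame with `gene`, `breadth`, `tau`, `mean`, `median`.
#' @export
expression_summaries <- function(mat, control_means) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression matrix must be non-negative")
  if (length(control_means) != ncol(mat)) {
    stop("one control mean per tissue is required")
  }
  masked <- sweep(mat, 2, control_means,
                  FUN = function(x, ctrl) ifelse(x < ctrl, 0, x))
  keep <- rowSums(masked) > 0
  masked <- masked[keep, , drop = FALSE]
  tot <- colSums(masked)
  if (any(tot == 0)) stop("a tissue has zero total signal after masking")
  norm <- sweep(masked, 2, tot, "/")
  nt <- ncol(norm)
  tau <- apply(norm, 1, function(x) {
    if (max(x) == 0) return(NA_real_)
    sum(1 - x / max(x)) / (nt - 1)
  })
  data.frame(gene = if (!is.null(rownames(norm))) rownames(norm) else
               which(keep),
             breadth = rowMeans(norm > 0),
             tau = tau,
             mean = rowMeans(norm),
             median = apply(norm, 1, stats::median),
             row.names = NULL, stringsAsFactors = FALSE)
}
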