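#' @name fitness
#' @title Negative-binomial fitness contrasts between growth stages
#'
#' @description
#' Counts are normalised by median-of-ratios size factors, per-strain
#' dispersions are estimated by method of moments with a fitted 1/mu trend
#' (final dispersion is the max of the raw estimate and the trend), and each
#' strain is tested for abundance change between two growth stages with a
#' Wald test on the log2 ratio of group means (delta-method standard error
#' under the NB variance `mu + alpha mu^2`). Strains changing at least
#' 1.5-fold with p < 0.05 are called haplo-proficient (up) or
#' haplo-insufficient (down).
NULL

#' Median-of-ratios size factors
#'
#' For each sample, the median over strains (restricted to strains with no
#' zero count in any sample) of the ratio of the strain's count to its
#' across-sample geometric mean.
#'
#' @param counts integer matrix, strains x samples.
#' @return numeric vector of per-sample size factors (all positive).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos))
    bf_validation_error(paste0(
      "no strain has positive counts in every sample; ",
      "consider adding a pseudocount before normalisation"))
  lg <- log(counts[allpos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  setNames(sf, colnames(counts))
}

#' Moment dispersion estimates with a fitted mean trend
#'
#' Raw per-strain dispersion `alpha = max(0, (s2 - mu) / mu^2)` from
#' within-group moments of normalised counts, pooled across groups; a trend
#' `alpha_tr(mu) = a0 + a1 / mu` is fit by least squares over strains with
#' positive raw estimates; the final dispersion is the larger of the raw
#' estimate and the trend value, which guards the test against
#' underestimated variances at low replication.
#'
#' @param counts integer matrix, strains x samples.
#' @param sf size factors from [size_factors()].
#' @param groups list of sample index/name vectors, one per group; every
#'   group needs at least 2 samples.
#' @return list of class `dispersion_estimate`: `alpha` (final, named),
#'   `alpha_raw`, `mu` (grand mean of normalised counts), `trend` (a0, a1).
#' @export
estimate_dispersion <- function(counts, sf, groups) {
  counts <- as.matrix(counts)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2))
    bf_validation_error("each group needs >= 2 replicates to estimate dispersion")
  norm <- sweep(counts, 2, sf, "/")
  ss <- 0; df <- 0
  for (g in groups) {
    x <- norm[, g, drop = FALSE]
    m <- rowMeans(x)
    ss <- ss + rowSums((x - m)^2)
    df <- df + (ncol(x) - 1)
  }
  s2 <- ss / df
  mu <- rowMeans(norm[, unlist(groups), drop = FALSE])
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  pos <- raw > 0 & mu > 0
  if (sum(pos) >= 2) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[pos]), raw[pos])
    a <- fit$coefficients
  } else {
    a <- c(0, 0)
  }
  trend <- pmax(0, ifelse(mu > 0, a[1] + a[2] / mu, 0))
  alpha <- pmax(raw, trend)
  structure(list(alpha = setNames(alpha, rownames(counts)),
                 alpha_raw = raw, mu = mu,
                 trend = c(a0 = unname(a[1]), a1 = unname(a[2]))),
            class = "dispersion_estimate")
}

#' Wald test of per-strain abundance change between two groups
#'
#' `log2fc = log2((meanB + c) / (meanA + c))` on normalised counts with
#' pseudocount `c = 0.5`; the standard error comes from the delta method
#' under `Var(K_ij) = mu_ij + alpha_i mu_ij^2` with `mu_ij = mean_g sf_j`;
#' p is the two-sided normal tail of the Wald statistic and `padj` is
#' Benjamini-Hochberg over all strains. Strains with zero counts in every
#' sample of both groups get `log2fc = 0`, `p = 1`.
#'
#' @param counts integer matrix, strains x samples.
#' @param sf size factors.
#' @param dispersion a `dispersion_estimate` (or numeric alpha vector).
#' @param group_a,group_b sample names/indices of the reference (A) and
#'   comparison (B) groups; log2fc is B relative to A.
#' @param pseudocount fold-change pseudocount, default 0.5.
#' @return data.frame of class `contrast_result`: strain_id, baseMean,
#'   log2fc, se, p, padj, call (all `NS` until [classify_calls()]).
#' @export
test_contrast <- function(counts, sf, dispersion, group_a, group_b,
                          pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (length(group_a) == 0 || length(group_b) == 0)
    bf_parameter_error("both groups must be non-empty")
  alpha <- if (inherits(dispersion, "dispersion_estimate"))
    dispersion$alpha else dispersion
  norm <- sweep(counts, 2, sf, "/")
  ka <- norm[, group_a, drop = FALSE]
  kb <- norm[, group_b, drop = FALSE]
  ma <- rowMeans(ka); mb <- rowMeans(kb)
  c0 <- pseudocount
  log2fc <- log2((mb + c0) / (ma + c0))
  sfa <- sf[group_a]; sfb <- sf[group_b]
  na <- length(group_a); nb <- length(group_b)
  # Var(mean_g) = (1/n^2) sum_j (mu/sf_j + alpha mu^2), mu = group mean
  va <- ma * sum(1 / sfa) / na^2 + alpha * ma^2 / na
  vb <- mb * sum(1 / sfb) / nb^2 + alpha * mb^2 / nb
  se <- sqrt(va / (ma + c0)^2 + vb / (mb + c0)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  zero <- rowSums(counts[, c(group_a, group_b), drop = FALSE]) == 0
  log2fc[zero] <- 0; se[zero] <- NA_real_; p[zero] <- 1
  res <- data.frame(
    strain_id = rownames(counts),
    baseMean = rowMeans(cbind(ka, kb)),
    log2fc = log2fc, se = se, p = p,
    padj = bh_fdr(p), call = "NS",
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Call haplo-proficient and haplo-insufficient strains
#'
#' HP if `log2fc >= log2(fold)` and `p < alpha_sig`; HI if
#' `log2fc <= -log2(fold)` and `p < alpha_sig`; otherwise NS. Calls use the
#' raw p-value; the BH-adjusted value is reported alongside.
#'
#' @param results a `contrast_result`.
#' @param alpha_sig significance threshold, default 0.05.
#' @param fold fold-change threshold on the natural scale, default 1.5
#'   (must exceed 1).
#' @param theta optional threshold directly on the log2 scale, overriding
#'   `log2(fold)` (e.g. 1.5 for the stricter intersection variant).
#' @return the results with `call` filled in.
#' @export
classify_calls <- function(results, alpha_sig = 0.05, fold = 1.5,
                           theta = NULL) {
  if (is.null(theta)) {
    if (fold <= 1) bf_parameter_error("fold threshold must exceed 1")
    theta <- log2(fold)
  }
  if (theta <= 0) bf_parameter_error("log2 threshold must be positive")
  results$call <- ifelse(
    results$p < alpha_sig & results$log2fc >= theta, "HP",
    ifelse(results$p < alpha_sig & results$log2fc <= -theta, "HI", "NS"))
  results
}

#' Tabulate exact intersections of per-condition call sets
#'
#' For every non-empty subset of conditions, counts the strains called in
#' exactly that subset of conditions (the tabulation behind UpSet-style
#' intersection plots).
#'
#' @param call_sets named list, one character vector of called strain ids
#'   per condition (>= 2 conditions).
#' @return data.frame `conditions` (subset label, `+`-joined), `degree`,
#'   `count`.
#' @export
intersect_calls <- function(call_sets) {
  if (length(call_sets) < 2)
    bf_parameter_error("need >= 2 conditions to intersect")
  conds <- names(call_sets)
  strains <- unique(unlist(call_sets))
  member <- vapply(call_sets, function(s) strains %in% s,
                   logical(length(strains)))
  if (length(strains) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r) paste(conds[r], collapse = "+"))
  n <- length(conds)
  subsets <- unlist(lapply(seq_len(n), function(k)
    combn(conds, k, paste, collapse = "+")))
  counts <- vapply(subsets, function(s) sum(key == s), 1L)
  data.frame(conditions = subsets,
             degree = lengths(strsplit(subsets, "+", fixed = TRUE)),
             count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call contrast between two growth stages of one condition
#'
#' Convenience wrapper: subsets the sheet, computes size factors and
#' dispersions on the contrasted samples, tests, and classifies.
#'
#' @param bc a `barseq_counts` or a counts matrix.
#' @param sheet a `sample_sheet` describing the columns.
#' @param condition condition to contrast.
#' @param from,to stage labels; log2fc is `to` relative to `from`.
#' @param alpha_sig,fold thresholds passed to [classify_calls()].
#' @return a classified `contrast_result`.
#' @export
contrast_stages <- function(bc, sheet, condition, from = "P", to = "B",
                            alpha_sig = 0.05, fold = 1.5) {
  counts <- if (inherits(bc, "barseq_counts")) bc$counts else as.matrix(bc)
  rows <- sheet[sheet$condition == condition &
                  sheet$stage %in% c(from, to), , drop = FALSE]
  a <- rows$sample_id[rows$stage == from]
  b <- rows$sample_id[rows$stage == to]
  if (length(a) == 0 || length(b) == 0)
    bf_parameter_error(paste0("no samples for ", condition, " ", from,
                              "->", to))
  sub <- counts[, c(a, b), drop = FALSE]
  sf <- size_factors(sub)
  disp <- estimate_dispersion(sub, sf, groups = list(a, b))
  res <- test_contrast(sub, sf, disp, group_a = a, group_b = b)
  classify_calls(res, alpha_sig = alpha_sig, fold = fold)
}
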