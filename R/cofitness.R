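#' @name cofitness
#' @title Co-fitness profiles, selection, clustering and class enrichment
#'
#' @description
#' Strains are profiled by their log2 fold changes across the eight
#' batch-vs-pool and late-vs-early steady-state comparisons (carbon- and
#' nitrogen-limited medium at 30 and 36 degrees C; LiCl conditions are
#' excluded by default). Responsive strains are selected by a per-strain
#' linear model on phase/nutrient/temperature, clustered by partitioning
#' around medoids, and each cluster is tested for enrichment of the SUT and
#' CUT classes with an exact binomial test under BH FDR control.
NULL

#' Canonical co-fitness comparison labels
#'
#' Phase (BP: batch vs pool; LE: late vs early steady state) x nutrient
#' (C/N limitation) x temperature (30/36), in fixed canonical order.
#'
#' @param include_licl also include the four LiCl comparisons (making 12).
#' @return character vector of comparison labels.
#' @export
cofitness_comparisons <- function(include_licl = FALSE) {
  base <- as.vector(outer(c("C_30", "C_36", "N_30", "N_36"),
                          c("BP", "LE"),
                          function(x, y) paste(y, x, sep = "_")))
  base <- base[order(rep(c(1, 2), each = 4))]
  if (include_licl)
    base <- c(base, as.vector(outer(c("C_30LiCl", "N_30LiCl"), c("BP", "LE"),
                                    function(x, y) paste(y, x, sep = "_"))))
  base
}

#' Assemble the strain x comparison fitness profile matrix
#'
#' Keeps strains present in every comparison; the number dropped is
#' recorded in the `dropped` attribute. Columns are re-ordered to the
#' canonical layout regardless of input order.
#'
#' @param contrasts named list of `contrast_result` data frames, one per
#'   comparison; names must cover [cofitness_comparisons()].
#' @param comparisons canonical column set to require.
#' @return numeric matrix (strains x comparisons) of log2 fold changes,
#'   with attribute `dropped`.
#' @export
build_profiles <- function(contrasts,
                           comparisons = cofitness_comparisons()) {
  miss <- setdiff(comparisons, names(contrasts))
  if (length(miss) > 0)
    bf_parameter_error(paste0("missing comparisons: ",
                              paste(miss, collapse = ", ")))
  contrasts <- contrasts[comparisons]
  ids <- lapply(contrasts, function(d) d$strain_id)
  keep <- Reduce(intersect, ids)
  total <- length(unique(unlist(ids)))
  m <- vapply(contrasts, function(d) d$log2fc[match(keep, d$strain_id)],
              numeric(length(keep)))
  if (length(keep) == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(keep, comparisons))
  rownames(m) <- keep
  attr(m, "dropped") <- total - length(keep)
  m
}

cofitness_design <- function(comparisons) {
  phase <- as.numeric(grepl("^LE", comparisons))
  nutrient <- as.numeric(grepl("_N_", comparisons))
  temperature <- as.numeric(grepl("_36", comparisons))
  cbind(intercept = 1, phase = phase, nutrient = nutrient,
        temperature = temperature)
}

#' Select strains with a significant response to the design variables
#'
#' Per strain, a gaussian linear model of the profile on coded covariates
#' phase (BP = 0, LE = 1), nutrient (C = 0, N = 1) and temperature (30 = 0,
#' 36 = 1), with two-sided p-values for each coefficient on the residual
#' degrees of freedom (4 for the eight standard comparisons), as a gaussian
#' GLM reports them. A strain is retained when any non-intercept
#' coefficient has p <= 0.05.
#'
#' @param profiles matrix from [build_profiles()].
#' @param alpha selection threshold, default 0.05.
#' @return data.frame with per-strain coefficients, p-values and
#'   `retained`; the design matrix is attached as attribute `design`.
#' @export
glm_select <- function(profiles, alpha = 0.05) {
  X <- cofitness_design(colnames(profiles))
  if (qr(X)$rank < ncol(X))
    bf_parameter_error("degenerate design: comparisons do not span the covariates")
  df <- nrow(X) - ncol(X)
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)
  B <- profiles %*% t(H)                      # n x 4 coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((profiles - fitted)^2)
  sigma2 <- rss / df
  se <- sqrt(outer(sigma2, diag(XtXi)))
  z <- ifelse(se > 0, B / se, ifelse(B == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(z), df = df)
  colnames(B) <- colnames(X)
  colnames(p) <- paste0("p_", colnames(X))
  retained <- apply(p[, -1, drop = FALSE] <= alpha, 1, any)
  out <- data.frame(strain_id = rownames(profiles), B, p,
                    retained = retained, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "design") <- X
  out
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' `q_(i) = min_(j >= i) min(1, p_(j) m / j)`, returned in the original
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    bf_parameter_error("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  q[order(o)]
}

#' Exact binomial two-sided enrichment test per cluster and class
#'
#' For each cluster and each class in `classes_tested`, tests the observed
#' class count `x` out of cluster size `n` against the background
#' proportion `p0` of that class among all clustered strains, using the
#' tail-doubling exact binomial test: twice the smaller of `P(X <= x)` and
#' `P(X >= x)`, capped at 1. q-values are BH over all cluster x class rows.
#'
#' @param assignment named integer vector, strain -> cluster id (e.g. from
#'   [pam_cluster()]).
#' @param classes named character vector, strain -> ncRNA class.
#' @param classes_tested classes to test, default SUT and CUT.
#' @return data.frame `cluster`, `class`, `x`, `n`, `p0`, `p_binomial`, `q`.
#' @export
cluster_enrichment <- function(assignment, classes,
                               classes_tested = c("SUT", "CUT")) {
  miss <- setdiff(names(assignment), names(classes))
  if (length(miss) > 0)
    bf_parameter_error("class labels missing for some clustered strains")
  cl <- classes[names(assignment)]
  rows <- list()
  for (cls in classes_tested) {
    p0 <- mean(cl == cls)
    if (p0 <= 0 || p0 >= 1) next   # class absent (or universal): untestable
    for (k in sort(unique(assignment))) {
      in_k <- assignment == k
      n <- sum(in_k)
      if (n == 0) { warning("empty cluster ", k, " skipped"); next }
      x <- sum(cl[in_k] == cls)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = k, class = cls, x = x, n = n, p0 = p0,
        p_binomial = binom_two_sided(x, n, p0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_binomial)
  out
}

#' Tail-doubling exact binomial test
#'
#' `p = min(1, 2 min(P(X <= x), P(X >= x)))` for `X ~ Binomial(n, p0)`.
#' When `x/n` equals `p0` exactly both tails cover the median, so p = 1.
#'
#' @param x observed successes.
#' @param n trials.
#' @param p0 null success probability, in (0, 1).
#' @return the two-sided p-value.
#' @export
binom_two_sided <- function(x, n, p0) {
  if (p0 <= 0 || p0 >= 1) bf_parameter_error("p0 must be in (0, 1)")
  lower <- pbinom(x, n, p0)
  upper <- pbinom(x - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' @importFrom stats pbinom
NULL

#' Split clusters by direction of fitness change
#'
#' Within each cluster, strains are sub-grouped by the sign of their mean
#' profile value (non-negative mean = sub-cluster 1, negative = 2).
#'
#' @param profiles profile matrix.
#' @param assignment cluster assignment over (a subset of) its rows.
#' @return data.frame `strain_id`, `cluster`, `subcluster`.
#' @export
subcluster_direction <- function(profiles, assignment) {
  mp <- rowMeans(profiles[names(assignment), , drop = FALSE])
  data.frame(strain_id = names(assignment),
             cluster = as.integer(assignment),
             subcluster = ifelse(mp >= 0, 1L, 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}
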