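#' @name pam
#' @title Partitioning around medoids (BUILD + SWAP) and silhouettes
#'
#' @description
#' Deterministic k-medoids clustering on Euclidean distances between
#' fitness profiles: greedy BUILD initialisation followed by exhaustive
#' SWAP until no medoid/non-medoid exchange reduces the total cost (sum of
#' distances of points to their nearest medoid). Ties are broken by the
#' lowest point index. The cluster count can be fixed or chosen
#' automatically by maximising the mean silhouette width over k = 2..10.
NULL

pam_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}

pam_build <- function(d, k) {
  n <- nrow(d)
  medoids <- which.min(colSums(d))[1]
  while (length(medoids) < k) {
    nearest <- apply(d[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(nearest - d[, j], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain)[1])  # which.max: lowest index on ties
  }
  sort(medoids)
}

pam_swap <- function(d, medoids, trace = NULL) {
  cost <- pam_cost(d, medoids)
  costs <- cost
  repeat {
    best <- list(delta = 0)
    for (m in medoids) {
      for (j in seq_len(nrow(d))) {
        if (j %in% medoids) next
        cand <- sort(c(setdiff(medoids, m), j))
        delta <- pam_cost(d, cand) - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, cand = cand)
      }
    }
    if (best$delta >= 0) break
    medoids <- best$cand
    cost <- cost + best$delta
    costs <- c(costs, cost)
  }
  list(medoids = medoids, cost = cost, costs = costs)
}

#' Mean silhouette width of a clustering
#'
#' @param d distance matrix.
#' @param assignment integer cluster ids per point.
#' @return list with `mean` and per-point widths `widths` (0 for singleton
#'   clusters, by convention).
#' @export
silhouette_width <- function(d, assignment) {
  n <- nrow(d)
  ks <- unique(assignment)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != assignment[i]], function(k)
      mean(d[i, assignment == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), widths = s)
}

#' Cluster fitness profiles by partitioning around medoids
#'
#' @param profiles numeric matrix (points x features) with unique rownames,
#'   or a symmetric distance matrix via `diss = TRUE`.
#' @param k cluster count, or `NULL` to choose k in `k_range` by maximum
#'   mean silhouette (ties to the smaller k).
#' @param k_range candidate k values for automatic selection.
#' @param diss treat `profiles` as a precomputed distance matrix.
#' @return list of class `pam_solution`: `k`, `assignment` (named integer,
#'   point -> cluster), `medoids` (rownames), `cost`, `cost_trace`
#'   (non-increasing SWAP costs), `silhouette` (mean width).
#' @export
pam_cluster <- function(profiles, k = NULL, k_range = 2:10, diss = FALSE) {
  d <- if (diss) as.matrix(profiles) else
    as.matrix(dist(profiles, method = "euclidean"))
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  fit_one <- function(k) {
    if (k < 2 || k > n) bf_parameter_error("k must be in [2, n]")
    sw <- pam_swap(d, pam_build(d, k))
    assignment <- apply(d[, sw$medoids, drop = FALSE], 1, which.min)
    list(k = k, assignment = setNames(assignment, ids),
         medoids = ids[sw$medoids], cost = sw$cost, cost_trace = sw$costs,
         silhouette = silhouette_width(d, assignment)$mean)
  }
  if (!is.null(k)) {
    out <- fit_one(k)
  } else {
    kk <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(kk) == 0) bf_parameter_error("no admissible k in k_range")
    fits <- lapply(kk, fit_one)
    sil <- vapply(fits, function(f) f$silhouette, numeric(1))
    out <- fits[[which.max(sil)]]
  }
  structure(out, class = "pam_solution")
}

#' @export
print.pam_solution <- function(x, ...) {
  cat("pam_solution: k =", x$k, " cost =", signif(x$cost, 6),
      " mean silhouette =", signif(x$silhouette, 4), "\n")
  print(table(cluster = x$assignment))
  invisible(x)
}
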