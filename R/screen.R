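#' @name screen
#' @title Colony-size screen: plate normalisation, mixture fit, scoring
#'
#' @description
#' Arrayed colony sizes are normalised per plate (division by the plate
#' median, then one round of multiplicative row/column median polish to
#' cancel positional effects), replicate positions are averaged per strain,
#' and the distribution of normalised sizes is modelled as a two-component
#' normal mixture fit by EM: one component for normal growth, one for
#' reduced fitness. Each strain's p-value is the two-sided tail probability
#' under the component closer to the wild-type mean; strains with p < 0.05
#' differ significantly from wild type.
NULL

#' Normalise colony plates and average replicates per strain
#'
#' @param plates data.frame with columns `plate_id`, `row`, `col`,
#'   `strain_id`, `size`, `is_wt` (as produced by [simulate_plates()] or
#'   loaded from a plate TSV). Missing colonies may be `NA` and propagate.
#' @return list: `strain_values` (named vector, replicate-averaged
#'   normalised size per strain), `wt_values` (normalised sizes at
#'   wild-type control positions), `colonies` (per-colony data frame with
#'   `norm_size`).
#' @export
normalize_plates <- function(plates) {
  need <- c("plate_id", "row", "col", "strain_id", "size", "is_wt")
  miss <- setdiff(need, names(plates))
  if (length(miss) > 0)
    bf_schema_error(paste0("plate table missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (nrow(plates) == 0) bf_parameter_error("need at least one plate")
  out <- plates
  out$norm_size <- NA_real_
  for (pid in unique(plates$plate_id)) {
    sel <- plates$plate_id == pid
    p <- plates[sel, , drop = FALSE]
    if (all(is.na(p$size)))
      bf_validation_error(paste0("plate ", pid, " has no colony sizes"))
    g <- matrix(NA_real_, nrow = max(p$row), ncol = max(p$col))
    g[cbind(p$row, p$col)] <- p$size
    g <- g / median(g, na.rm = TRUE)
    rmed <- apply(g, 1, median, na.rm = TRUE)
    g <- g / rmed                       # one round of row polish...
    cmed <- apply(g, 2, median, na.rm = TRUE)
    g <- sweep(g, 2, cmed, "/")         # ...then column polish
    out$norm_size[sel] <- g[cbind(p$row, p$col)]
  }
  non_wt <- out[!out$is_wt, , drop = FALSE]
  strain_values <- tapply(non_wt$norm_size, non_wt$strain_id,
                          mean, na.rm = TRUE)
  strain_values <- setNames(as.numeric(strain_values), names(strain_values))
  list(strain_values = strain_values,
       wt_values = out$norm_size[out$is_wt],
       colonies = out)
}

#' Fit a two-component normal mixture by EM
#'
#' Initialised by splitting at the 10th percentile (component 2 = lower
#' tail, the putative reduced-fitness class); iterates standard EM until
#' the log-likelihood gain drops below `tol` or `max_iter` is reached, with
#' standard deviations clamped at `sigma_floor`. Non-convergence is flagged
#' (`converged = FALSE`), not an error.
#'
#' @param values numeric vector of at least 10 finite values.
#' @param max_iter,tol EM stopping parameters.
#' @param sigma_floor lower bound for both standard deviations.
#' @return list of class `mixture_fit`: `pi` (weight of component 1),
#'   `mu`, `sigma` (length-2), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`.
#' @export
fit_mixture <- function(values, max_iter = 1000L, tol = 1e-8,
                        sigma_floor = 1e-3) {
  x <- values[is.finite(values)]
  if (length(x) < 10)
    bf_parameter_error("need >= 10 finite values to fit the mixture")
  if (sd(x) == 0) {
    return(structure(list(pi = 0.5, mu = c(x[1], x[1]),
                          sigma = c(sigma_floor, sigma_floor),
                          loglik = sum(dnorm(x, x[1], sigma_floor, log = TRUE)),
                          loglik_trace = numeric(0), iterations = 0L,
                          converged = TRUE),
                     class = "mixture_fit"))
  }
  q10 <- quantile(x, 0.1, names = FALSE)
  low <- x <= q10
  if (sum(low) < 2 || sum(!low) < 2) low <- x <= median(x)
  mu <- c(mean(x[!low]), mean(x[low]))
  sg <- pmax(c(sd(x[!low]), sd(x[low])), sigma_floor)
  pi1 <- mean(!low)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d1 <- pi1 * dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(loglik) && ll - loglik < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    n1 <- sum(r1); n2 <- length(x) - n1
    pi1 <- n1 / length(x)
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                 sum((1 - r1) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, sigma_floor)
  }
  structure(list(pi = pi1, mu = mu, sigma = sg, loglik = loglik,
                 loglik_trace = trace, iterations = it,
                 converged = converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: pi1=%.3f mu=(%.4f, %.4f) sigma=(%.4f, %.4f) %s in %d iters\n",
    x$pi, x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Score strains against the wild-type-proximal mixture component
#'
#' The reference component is the one whose mean is nearer `wt_mean`; each
#' strain's p-value is `2 (1 - Phi(|v - mu_wt| / sigma_wt))` (or the
#' one-sided tail on request). Significant means p < 0.05, strictly.
#'
#' @param fit a `mixture_fit`.
#' @param values named vector of replicate-averaged normalised sizes.
#' @param wt_mean wild-type reference mean (e.g. mean of control positions,
#'   or the global median when no controls exist).
#' @param alpha significance threshold.
#' @param one_sided use the one-sided lower tail instead.
#' @return data.frame `strain_id`, `norm_size`, `p`, `significant`,
#'   `direction` (`bigger`/`smaller`/`none`); the chosen component index is
#'   attached as attribute `wt_component`.
#' @export
score_strains <- function(fit, values, wt_mean, alpha = 0.05,
                          one_sided = FALSE) {
  wt_component <- which.min(abs(fit$mu - wt_mean))
  mu <- fit$mu[wt_component]
  sg <- fit$sigma[wt_component]
  v <- as.numeric(values)
  p <- if (one_sided) pnorm((v - mu) / sg)
       else 2 * pnorm(-abs(v - mu) / sg)
  significant <- p < alpha
  direction <- ifelse(!significant, "none",
                      ifelse(v > mu, "bigger", "smaller"))
  out <- data.frame(strain_id = names(values), norm_size = v, p = p,
                    significant = significant, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "wt_component") <- wt_component
  out
}

#' Run the whole colony screen
#'
#' Normalises plates, averages replicates, fits the mixture and scores
#' strains against the wild-type-proximal component. The wild-type mean is
#' the mean of normalised control positions when present, else the global
#' median of strain values.
#'
#' @param plates plate data.frame (see [normalize_plates()]).
#' @param ... passed to [fit_mixture()].
#' @return list: `calls` (scored strains), `fit`, `normalized`.
#' @export
colony_screen <- function(plates, ...) {
  nz <- normalize_plates(plates)
  wt_mean <- if (length(nz$wt_values) > 0) mean(nz$wt_values, na.rm = TRUE)
             else median(nz$strain_values, na.rm = TRUE)
  fit <- fit_mixture(nz$strain_values, ...)
  calls <- score_strains(fit, nz$strain_values, wt_mean)
  list(calls = calls, fit = fit, normalized = nz)
}

#' Trapezoidal area under a growth curve
#'
#' @param curve a `growth_curve` (data.frame `time`, `od`) with at least
#'   two strictly increasing time points.
#' @return the integral of OD over time (OD x hours).
#' @export
growth_auc <- function(curve) {
  if (nrow(curve) < 2) bf_parameter_error("need >= 2 points for AUC")
  if (any(diff(curve$time) <= 0))
    bf_validation_error("times must be strictly increasing")
  pracma::trapz(curve$time, curve$od)
}
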