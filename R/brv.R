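#' Beat-rate-variability measures from a beat series
#'
#' Computes the inter-beat-interval statistics used in Poincare-plot
#' analysis, in which each IBI(n+1) is plotted against its predecessor
#' IBI(n) and an ellipse is fitted with its centre at the centroid: SD1
#' (the semi-axis perpendicular to the identity line) captures short-term
#' variability, SD2 (the semi-axis along the identity line) long-term
#' variability. All variances use the sample (n-1) denominator,
#' consistent with mean +/- SD reporting:
#' \deqn{SD1^2 = Var(IBI_{n+1} - IBI_n) / 2, \quad
#'       SD2^2 = 2 Var(IBI) - SD1^2}
#' (`SD2^2` floored at 0), and `CV = 100 * SD(IBI) / mean(IBI)`.
#'
#' @param beats A [beat_series()] with >= 4 beats (>= 3 IBIs).
#' @param n_bins Number of histogram bins over the IBI range (display
#'   only; the bimodality decision does not use the histogram).
#' @return An object of class `brv`: `mean_ibi_s`, `cv_pct`, `sd1_s`,
#'   `sd2_s`, `poincare_centroid`, `histogram` (`breaks`, `counts`), and
#'   the raw `ibis_s`.
#' @export
compute_brv <- function(beats, n_bins = 40) {
  stopifnot(inherits(beats, "beat_series"))
  ibis <- beats$ibis_s
  if (length(ibis) < 3L) stop("need >= 4 beats (>= 3 IBIs)")
  m <- mean(ibis)
  v <- stats::var(ibis)
  sd1 <- sqrt(stats::var(diff(ibis)) / 2)
  sd2 <- sqrt(max(2 * v - sd1^2, 0))
  h <- if (diff(range(ibis)) > 0)
    graphics::hist(ibis, breaks = seq(min(ibis), max(ibis), length.out = n_bins + 1L),
                   plot = FALSE)
  else list(breaks = c(ibis[1L] - 1e-9, ibis[1L] + 1e-9),
            counts = length(ibis))
  structure(list(mean_ibi_s = m, cv_pct = 100 * sqrt(v) / m,
                 sd1_s = sd1, sd2_s = sd2,
                 poincare_centroid = c(m, m),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 ibis_s = ibis),
            class = "brv")
}

#' @export
print.brv <- function(x, ...) {
  cat(sprintf("<brv> mean IBI %.3f s, CV %.2f%%, SD1 %.4f s, SD2 %.4f s (n=%d IBIs)\n",
              x$mean_ibi_s, x$cv_pct, x$sd1_s, x$sd2_s, length(x$ibis_s)))
  invisible(x)
}

#' Poincare plot of a BRV result
#'
#' Plots IBI(n+1) against IBI(n) with the fitted ellipse (semi-axes SD1
#' perpendicular to and SD2 along the identity line, centred at the
#' centroid).
#'
#' @param x A `brv` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.brv <- function(x, ...) {
  ib <- x$ibis_s
  p <- cbind(ib[-length(ib)], ib[-1L])
  graphics::plot(p, xlab = "IBI(n) [s]", ylab = "IBI(n+1) [s]",
                 asp = 1, ...)
  th <- seq(0, 2 * pi, length.out = 181L)
  u <- cbind(cos(th), sin(th)) %*% diag(c(x$sd2_s, x$sd1_s))
  rot <- matrix(c(1, 1, -1, 1) / sqrt(2), 2L)
  e <- t(rot %*% t(u)) + rep(x$poincare_centroid, each = length(th))
  graphics::lines(e, col = "red")
  graphics::abline(0, 1, lty = 3L)
  invisible(x)
}

# 1-D Gaussian mixture by BIC with a variance floor; deterministic
# (mclust's EM initializes from model-based hierarchical clustering).
fit_ibi_mixture <- function(ibis, G) {
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(ibis, G = G, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  fit
}

#' Detect bimodal firing from the IBI distribution
#'
#' Fits 1- and 2-component Gaussian mixtures to the IBI distribution and
#' declares bimodal firing if (a) the 2-component model has the better BIC
#' and (b) the component means are separated by more than twice the pooled
#' within-component SD — the "two clouds with minimal overlap" signature
#' of a bimodally firing preparation. Component variances are floored at
#' (1 ms)^2 against degenerate fits.
#'
#' @param beats A [beat_series()] with >= 30 IBIs.
#' @param separation_factor Required mode separation in pooled-SD units.
#' @return List with `bimodal` (logical) and `mode_estimates_s` (one or
#'   two component means).
#' @export
detect_bimodality <- function(beats, separation_factor = 2) {
  stopifnot(inherits(beats, "beat_series"))
  ibis <- beats$ibis_s
  if (length(ibis) < 30L) stop("need >= 30 IBIs")
  if (stats::sd(ibis) < 1e-3)   # effectively constant: unimodal by definition
    return(list(bimodal = FALSE, mode_estimates_s = mean(ibis)))
  f1 <- fit_ibi_mixture(ibis, 1L)
  f2 <- fit_ibi_mixture(ibis, 2L)
  if (is.null(f2) || is.null(f1))
    return(list(bimodal = FALSE, mode_estimates_s = mean(ibis)))
  floor_var <- 1e-6
  mu <- as.numeric(f2$parameters$mean)
  s2 <- pmax(as.numeric(f2$parameters$variance$sigmasq), floor_var)
  pr <- as.numeric(f2$parameters$pro)
  pooled_sd <- sqrt(sum(pr * s2))
  sep_ok <- abs(diff(mu)) > separation_factor * pooled_sd
  bic_ok <- f2$bic > f1$bic    # mclust BIC: larger is better
  if (bic_ok && sep_ok)
    list(bimodal = TRUE, mode_estimates_s = sort(mu))
  else
    list(bimodal = FALSE, mode_estimates_s = as.numeric(f1$parameters$mean))
}

#' Number of clouds in the Poincare plot
#'
#' Clusters the lag-1 points (IBI(n), IBI(n+1)) with 2-D Gaussian mixtures
#' over k = 1..`k_max` components and returns the BIC-selected k. A
#' strictly alternating bimodal process yields 2 (off-diagonal) clouds; a
#' bimodal process with independent 50% switching yields the 4-cloud
#' pattern.
#'
#' @param beats A [beat_series()] with >= 30 IBIs.
#' @param k_max Maximum number of clouds considered.
#' @return Integer cloud count.
#' @export
poincare_cloud_count <- function(beats, k_max = 4) {
  stopifnot(inherits(beats, "beat_series"))
  ibis <- beats$ibis_s
  if (length(ibis) < 30L) stop("need >= 30 IBIs")
  p <- cbind(ibis[-length(ibis)], ibis[-1L])
  if (stats::sd(ibis) < 1e-3) return(1L)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(p, G = seq_len(k_max), verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(1L)
  as.integer(fit$G)
}
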