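#' Fit a three-component Gaussian mixture to ROH lengths
#'
#' Fits a univariate, unequal-variance three-component Gaussian mixture to
#' segment lengths (kb scale by default) by EM, taking the best of several
#' initializations by log-likelihood. Components are reported sorted by
#' mean, and the two class boundaries are the points where the
#' posterior-argmax component switches between adjacent components: the root
#' of the weighted-density equality (a quadratic in x) lying between the two
#' means, with a fine-grid scan fallback when no root lies there.
#'
#' The first initialization places component means at the 25/50/75%
#' quantiles; the remaining `n_init - 1` start from random seeded draws of
#' centers (k-means-style), so the headline fit is deterministic under
#' `seed`.
#'
#' @param lengths_kb numeric vector of segment lengths in kb (>= 30 values,
#'   all positive, not all equal).
#' @param seed integer seed for the random restarts.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param max_iter maximum EM iterations per initialization.
#' @param n_init number of initializations.
#' @param log_scale if `TRUE`, fit on log(kb) and transform the boundaries
#'   back; means/sds are then reported on the log scale.
#' @return list of class `roh_mixture`: `weights`, `means_kb`, `sds_kb`
#'   (sorted by mean), `boundaries_kb` (length 2), `loglik`, `n_iter`,
#'   `converged`, `log_scale`.
#' @export
fit_length_mixture <- function(lengths_kb, seed = 1L, tol = 1e-6,
                               max_iter = 500L, n_init = 10L,
                               log_scale = FALSE) {
  x <- as.numeric(lengths_kb)
  if (length(x) < 30) stop("need at least 30 lengths")
  if (any(!is.finite(x)) || any(x <= 0)) stop("lengths must be positive")
  if (length(unique(x)) == 1) stop("degenerate input: all lengths equal")
  if (log_scale) x <- log(x)

  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (init in seq_len(n_init)) {
    mu0 <- if (init == 1) as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75)))
    else sort(sample(x, 3))
    if (length(unique(mu0)) < 3)
      mu0 <- mu0 + stats::sd(x) * 0.01 * (0:2)
    fit <- em_gmm3(x, mu0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations")

  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; sd_ <- best$sd[ord]
  b <- c(component_boundary(w[1], mu[1], sd_[1], w[2], mu[2], sd_[2]),
         component_boundary(w[2], mu[2], sd_[2], w[3], mu[3], sd_[3]))
  if (log_scale) b <- exp(b)
  structure(list(weights = w, means_kb = mu, sds_kb = sd_,
                 boundaries_kb = b, loglik = best$loglik,
                 n_iter = best$n_iter, converged = best$converged,
                 log_scale = log_scale),
            class = "roh_mixture")
}

#' @export
print.roh_mixture <- function(x, ...) {
  cat("3-component Gaussian mixture (", if (x$log_scale) "log-kb" else "kb",
      " scale)\n", sep = "")
  cat(sprintf("  means: %s\n", paste(signif(x$means_kb, 6), collapse = ", ")))
  cat(sprintf("  boundaries: %s kb\n",
              paste(signif(x$boundaries_kb, 6), collapse = " / ")))
  invisible(x)
}

# internal: EM for a univariate 3-component unequal-variance mixture.
# The log-likelihood is checked to be non-decreasing every iteration.
em_gmm3 <- function(x, mu, tol, max_iter) {
  K <- 3L
  n <- length(x)
  w <- rep(1 / K, K)
  sd_ <- rep(stats::sd(x) / K + 1e-8, K)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  sd_floor <- max(diff(range(x)) * 1e-6, 1e-8)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(x, mu[k], sd_[k]), numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    if (ll < ll_old - 1e-8 * abs(ll_old))
      stop("internal error: EM log-likelihood decreased")
    resp <- dens / rowsum_
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sd_ <- pmax(sd_, sd_floor)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd_, loglik = ll, n_iter = iter,
       converged = converged)
}

# internal: boundary between two adjacent (by mean) weighted Gaussians:
# solve w1 N(x; m1, s1) = w2 N(x; m2, s2), keep the root in (m1, m2);
# grid-scan fallback when no analytic root lies between the means.
component_boundary <- function(w1, m1, s1, w2, m2, s2) {
  # log equality: -(x-m1)^2/(2 s1^2) + log(w1/s1) = -(x-m2)^2/(2 s2^2) + log(w2/s2)
  # rearranged to A x^2 + B x + C = 0
  A <- 0.5 * (1 / s2^2 - 1 / s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- 0.5 * (m2^2 / s2^2 - m1^2 / s1^2) + log(w1 / s1) - log(w2 / s2)
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside)) return(inside[1])
  # fallback: finest point where the posterior argmax flips
  grid <- seq(m1, m2, length.out = 10001)
  d1 <- w1 * stats::dnorm(grid, m1, s1)
  d2 <- w2 * stats::dnorm(grid, m2, s2)
  flip <- which(d2 >= d1)
  if (length(flip)) grid[flip[1]] else (m1 + m2) / 2
}

#' Classify ROH segments into short/medium/long
#'
#' Half-open rule with boundary ties assigned upward: short if
#' `length_kb < b1`, medium if `b1 <= length_kb < b2`, long otherwise.
#'
#' @param segments segment data.frame.
#' @param boundaries_kb increasing length-2 numeric (kb), e.g. from
#'   [fit_length_mixture()].
#' @return `segments` with the `class` column filled; the class share table
#'   is attached as attribute `"shares"`.
#' @export
classify_segments <- function(segments, boundaries_kb) {
  stopifnot(length(boundaries_kb) == 2, diff(boundaries_kb) > 0)
  kb <- segments$length_bp / 1000
  cls <- ifelse(kb < boundaries_kb[1], "short",
                ifelse(kb < boundaries_kb[2], "medium", "long"))
  segments$class <- cls
  attr(segments, "shares") <-
    prop.table(table(factor(cls, levels = c("short", "medium", "long"))))
  segments
}
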