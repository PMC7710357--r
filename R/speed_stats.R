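## Run-speed summaries and 1- vs 2-component Gaussian modelling of the
## run-speed distribution. Mirroring common practice for this measurement,
## the default fit is least squares of a (sum of) Gaussian curve(s) against
## the binned frequency distribution of speeds (bin width 0.1 um/s), with
## the 1- and 2-component models compared by the extra sum-of-squares
## F test. A maximum-likelihood (EM) mode exists for cross-checking.

#' Per-cell and pooled run-speed summaries
#'
#' @param runs run table with `speed_um_s` and optionally a `cell` column.
#' @return list with `per_cell` (cell, n_runs, mean_speed) and `pooled`
#'   (all individual run speeds).
#' @export
per_cell_speed_stats <- function(runs) {
  if (is.null(runs$cell)) runs$cell <- 1L
  runs <- runs[!is.na(runs$speed_um_s), ]
  cells <- unique(runs$cell)
  per_cell <- do.call(rbind, lapply(cells, function(cl) {
    sp <- runs$speed_um_s[runs$cell == cl]
    if (!length(sp)) return(NULL)
    data.frame(cell = cl, n_runs = length(sp), mean_speed = mean(sp))
  }))
  list(per_cell = per_cell, pooled = runs$speed_um_s)
}

#' Fit a 1- or 2-component Gaussian model of run speeds
#'
#' Bins the speeds at `bin_width` and fits the sum of `k` Gaussian curves
#' `A_i * exp(-(x - mu_i)^2 / (2 sd_i^2))` to the bin counts by least
#' squares, with multi-start initialization (means at the 25th/75th
#' percentiles for `k = 2`, plus deterministic jittered restarts).
#' Component weights are the area fractions `A_i sd_i / sum(A_j sd_j)`.
#' Degrees of freedom are the number of bins minus the number of free
#' parameters. A fit whose two components collapse onto each other (means
#' closer than one bin width or a vanishing weight) is flagged degenerate.
#'
#' @param speeds numeric vector of run speeds, um/s.
#' @param k 1 or 2 components.
#' @param bin_width histogram bin width, um/s.
#' @param n_starts number of jittered restarts for `k = 2`.
#' @param min_n minimum sample size guard for `k = 2`.
#' @param method `"ls"` (binned least squares, default) or `"mle"`
#'   (EM maximum likelihood cross-check; SSE is still reported on the
#'   binned representation of the MLE solution).
#' @return an object of class `speed_mixture_fit`.
#' @export
fit_speed_mixture <- function(speeds, k = 2L, bin_width = 0.1,
                              n_starts = 10L, min_n = 50L,
                              method = c("ls", "mle")) {
  method <- match.arg(method)
  speeds <- speeds[!is.na(speeds)]
  k <- as.integer(k)
  stopifnot(k %in% c(1L, 2L))
  if (k == 2L && length(speeds) < min_n)
    stop_config("two-component fit requires at least %d speeds, got %d",
                min_n, length(speeds))
  breaks <- seq(floor(min(speeds) / bin_width) * bin_width,
                ceiling(max(speeds) / bin_width) * bin_width,
                by = bin_width)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + bin_width)
  h <- hist(speeds, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts

  if (method == "mle") {
    par <- mixture_em(speeds, k)
    ## express on the binned scale: A_i = n * w_i * bw / (sd_i sqrt(2 pi))
    A <- length(speeds) * par$w * bin_width / (par$sd * sqrt(2 * pi))
    pars <- list(A = A, mu = par$mean, sd = par$sd)
    sse <- sum((y - mix_curve(x, pars))^2)
    converged <- TRUE
  } else {
    fit <- ls_mixture_fit(x, y, k, n_starts, bin_width)
    pars <- fit$pars; sse <- fit$sse; converged <- fit$converged
    if (!converged)
      stop_config("mixture fit did not converge (best SSE %.4g)", sse)
  }
  ord <- order(pars$mu)
  A <- unname(pars$A[ord]); mu <- unname(pars$mu[ord])
  sdv <- unname(pars$sd[ord])
  w <- A * sdv / sum(A * sdv)
  ## collapse modes: components merged, a component with next to no mass,
  ## or a component squeezed to the one-bin resolution floor (boundary
  ## solution chasing a single bin's count fluctuation)
  degenerate <- k == 2L &&
    (abs(diff(mu)) < bin_width || any(w < 0.02) ||
       any(sdv <= bin_width * 1.001))
  out <- list(k = k, means = mu, sds = sdv, weights = w, amplitudes = A,
              sse = sse, df = length(y) - 3L * k, n = length(speeds),
              bin_width = bin_width, breaks = breaks, counts = y,
              mids = x, method = method, degenerate = degenerate)
  class(out) <- "speed_mixture_fit"
  out
}

mix_curve <- function(x, pars) {
  out <- 0
  for (i in seq_along(pars$A))
    out <- out + pars$A[i] * exp(-(x - pars$mu[i])^2 / (2 * pars$sd[i]^2))
  out
}

ls_mixture_fit <- function(x, y, k, n_starts, bin_width) {
  rng_x <- range(x)
  sd0 <- max(bin_width, diff(rng_x) / 6)
  qs <- cumsum(y) / sum(y)
  qat <- function(p) x[which.min(abs(qs - p))]
  starts <- list()
  if (k == 1L) {
    mu0 <- sum(x * y) / sum(y)
    starts[[1]] <- list(A = max(y), mu = mu0, sd = sd0)
    starts[[2]] <- list(A = max(y), mu = qat(0.5), sd = sd0 / 2)
  } else {
    base_mu <- c(qat(0.25), qat(0.75))
    ## deterministic jitter grid around the percentile starts
    jit <- seq(-1, 1, length.out = max(2L, n_starts)) * diff(rng_x) / 8
    for (j in jit) {
      starts[[length(starts) + 1L]] <-
        list(A = rep(max(y) / 2, 2), mu = base_mu + c(-j, j),
             sd = rep(sd0, 2))
    }
  }
  best <- list(sse = Inf, pars = NULL)
  for (st in starts) {
    p0 <- unlist(st)
    obj <- function(p) {
      pars <- list(A = p[1:k], mu = p[(k + 1):(2 * k)],
                   sd = p[(2 * k + 1):(3 * k)])
      r <- y - mix_curve(x, pars)
      sum(r^2)
    }
    ## a component narrower than one bin is unresolvable at this binning
    ## and only chases single-bin count fluctuations; floor the sd there
    lo <- c(rep(0, k), rep(rng_x[1] - 1, k), rep(bin_width, k))
    hi <- c(rep(Inf, k), rep(rng_x[2] + 1, k), rep(diff(rng_x) + 1, k))
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$value < best$sse) {
      best <- list(sse = res$value,
                   pars = list(A = res$par[1:k],
                               mu = res$par[(k + 1):(2 * k)],
                               sd = res$par[(2 * k + 1):(3 * k)]),
                   converged = res$convergence == 0)
    }
  }
  if (is.null(best$pars)) return(list(sse = Inf, pars = NULL, converged = FALSE))
  best$converged <- TRUE
  best
}

## plain EM for a k-component normal mixture (cross-check mode)
mixture_em <- function(xs, k, max_iter = 500L, tol = 1e-8) {
  qs <- quantile(xs, probs = seq(0.25, 0.75, length.out = k))
  mu <- as.numeric(qs); sdv <- rep(sd(xs) / k, k); w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- sapply(seq_len(k), function(i) w[i] * dnorm(xs, mu[i], sdv[i]))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    g <- dens / tot
    nk <- colSums(g)
    w <- nk / length(xs)
    mu <- colSums(g * xs) / nk
    sdv <- sqrt(colSums(g * (xs - rep(mu, each = length(xs)))^2) / nk)
    sdv <- pmax(sdv, 1e-4)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, mean = mu, sd = sdv, loglik = ll_old)
}

#' @export
print.speed_mixture_fit <- function(x, ...) {
  cat("<speed_mixture_fit>", x$k, "component(s),", x$n, "speeds, bin width",
      x$bin_width, "um/s", if (x$method == "mle") "(MLE)" else "", "\n")
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: mean %.3f um/s, sd %.3f, weight %.3f\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  cat(sprintf("  SSE %.4g on %d df%s\n", x$sse, x$df,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
summary.speed_mixture_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.speed_mixture_fit <- function(object, ...) {
  stats::setNames(
    c(object$means, object$sds, object$weights),
    c(paste0("mean", seq_len(object$k)), paste0("sd", seq_len(object$k)),
      paste0("weight", seq_len(object$k))))
}

#' @export
predict.speed_mixture_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$mids
  mix_curve(x, list(A = object$amplitudes, mu = object$means,
                    sd = object$sds))
}

#' @export
fitted.speed_mixture_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.speed_mixture_fit <- function(object, ...) {
  object$counts - fitted(object)
}

#' @export
plot.speed_mixture_fit <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", lwd = 3, col = "grey70",
                 xlab = "run speed (um/s)", ylab = "runs per bin", ...)
  xs <- seq(min(x$breaks), max(x$breaks), length.out = 400)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  for (i in seq_len(x$k))
    graphics::lines(xs, x$amplitudes[i] *
                      exp(-(xs - x$means[i])^2 / (2 * x$sds[i]^2)),
                    lty = 2)
  invisible(x)
}

#' Extra sum-of-squares F test between nested mixture fits
#'
#' Compares the 1-component fit against the nested 2-component fit on the
#' same binned data: `F = ((SSE1 - SSE2) / (df1 - df2)) / (SSE2 / df2)`,
#' with the p value from the F distribution. If the richer model fits no
#' better, F is clamped at 0 and the simpler model preferred. A degenerate
#' 2-component fit (collapsed components, see [fit_speed_mixture()]) is not
#' accepted as the preferred model regardless of p, since it does not
#' represent a genuine second speed population.
#'
#' @param fit1 the `k = 1` fit.
#' @param fit2 the `k = 2` fit (same data and binning).
#' @param alpha significance level for preferring `k = 2`.
#' @return object of class `model_comparison` with `F`, `df_num`,
#'   `df_den`, `p`, `preferred` (1 or 2).
#' @export
extra_ss_ftest <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "speed_mixture_fit"),
            inherits(fit2, "speed_mixture_fit"),
            fit1$k == 1L, fit2$k == 2L)
  if (fit1$n != fit2$n || abs(fit1$bin_width - fit2$bin_width) > 1e-12)
    stop_config("F test requires fits to the same data and binning")
  df_num <- fit1$df - fit2$df
  df_den <- fit2$df
  if (fit2$sse >= fit1$sse) {
    F <- 0; p <- 1
  } else {
    F <- ((fit1$sse - fit2$sse) / df_num) / (fit2$sse / df_den)
    p <- pf(F, df_num, df_den, lower.tail = FALSE)
  }
  preferred <- if (p < alpha && !isTRUE(fit2$degenerate)) 2L else 1L
  out <- list(F = F, df_num = df_num, df_den = df_den, p = p,
              alpha = alpha, preferred = preferred,
              fit2_degenerate = isTRUE(fit2$degenerate))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("extra sum-of-squares F = %.4g on (%d, %d) df, p = %.4g\n",
              x$F, x$df_num, x$df_den, x$p))
  cat("  preferred model:", x$preferred, "component(s)\n")
  invisible(x)
}

#' Run speeds binned by distance from a reference point
#'
#' Assigns each run to a distance bin by the distance of its start point
#' from `ref` and reports per-bin mean, SD and count of run speeds. Empty
#' bins are reported with `n = 0` and NA statistics.
#'
#' @param runs run table with `start_x`, `start_y`, `speed_um_s`.
#' @param ref length-2 reference point (e.g. the Golgi centroid),
#'   micrometres.
#' @param breaks distance bin edges, micrometres.
#' @return data frame with `bin_lo`, `bin_hi`, `n`, `mean_speed`,
#'   `sd_speed`.
#' @export
speed_by_distance <- function(runs, ref, breaks) {
  d <- sqrt((runs$start_x - ref[1])^2 + (runs$start_y - ref[2])^2)
  bin <- cut(d, breaks = breaks, right = FALSE, include.lowest = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$n <- as.vector(table(bin))
  sp <- split(runs$speed_um_s, bin)
  out$mean_speed <- vapply(sp, function(v) if (length(v)) mean(v) else NA_real_,
                           numeric(1))
  out$sd_speed <- vapply(sp, function(v) if (length(v) > 1) sd(v) else NA_real_,
                         numeric(1))
  rownames(out) <- NULL
  out
}
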