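#' Choose a truncation point from a bimodal trans-count distribution
#'
#' Trans-ligation totals of captured fragments are typically bimodal: a
#' low-count component of failed baits (stochastic noise) and a high-count
#' component of working baits (signal). The valley heuristic histograms
#' `log1p(n_trans)`, smooths the bin counts with a centred moving average,
#' and returns the count value at the deepest bin between the two largest
#' smoothed modes. A manual truncation point can be supplied instead.
#'
#' @param n_trans Integer vector of per-fragment trans counts (one
#'   replicate); at least 50 values for the valley method.
#' @param method `"valley"` (default) or `"manual"`.
#' @param manual_t Truncation point when `method = "manual"`.
#' @param binwidth Histogram bin width on the `log1p` scale; default 1.
#' @param window Moving-average window in bins (odd); default 3. Wider
#'   windows over-smooth the short log-scale histogram and can merge or
#'   displace the two mixture modes.
#' @return Integer truncation point `t`. A unimodal histogram yields
#'   `t = 0` with a warning (no truncation).
#' @export
select_truncation_point <- function(n_trans, method = c("valley", "manual"),
                                    manual_t = NULL, binwidth = 1,
                                    window = 3) {
  method <- match.arg(method)
  if (method == "manual") {
    stopifnot(!is.null(manual_t), manual_t >= 0)
    return(as.integer(manual_t))
  }
  stopifnot(length(n_trans) >= 50)
  lx <- log1p(n_trans)
  breaks <- seq(0, max(lx) + binwidth, by = binwidth)
  counts <- tabulate(findInterval(lx, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1)
  sm <- moving_average(counts, window)
  modes <- local_maxima(sm)
  # ignore minor wiggles: a mode must carry at least 10% of the main
  # mode's (smoothed) mass to count as a mixture component
  modes <- modes[sm[modes] >= 0.1 * max(sm)]
  if (length(modes) < 2) {
    warning("trans-count histogram looks unimodal; no truncation (t = 0)")
    return(0L)
  }
  top2 <- sort(modes[order(sm[modes], decreasing = TRUE)][1:2])
  between <- seq(top2[1] + 1, top2[2] - 1)
  if (length(between) == 0) {
    warning("modes adjacent; no truncation (t = 0)")
    return(0L)
  }
  valley <- between[which.min(sm[between])]
  # the dip must be real: a shallow saddle is treated as unimodal
  if (sm[valley] > 0.8 * min(sm[top2])) {
    warning("no clear valley between modes; no truncation (t = 0)")
    return(0L)
  }
  mid <- (breaks[valley] + breaks[valley + 1]) / 2
  as.integer(floor(expm1(mid)))
}

moving_average <- function(x, window) {
  stopifnot(window >= 1)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n == 1) return(1L)
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > left & x >= right)
}

#' Maximum-likelihood fit of a left-truncated negative binomial
#'
#' Fits the upper (signal) component of a trans-count distribution: the
#' likelihood of each observation `x >= t` is `P(X = x) / P(X >= t)` under
#' an untruncated NB(mu, size), maximised over `(log mu, log size)` with
#' three starts (method of moments, mu doubled, mu halved). With `t = 0`
#' this reduces to the ordinary NB maximum-likelihood fit.
#'
#' @param n_trans Integer vector of trans counts.
#' @param t Truncation point; only observations `>= t` enter the fit
#'   (at least 30 required).
#' @param reltol Relative convergence tolerance; default 1e-8.
#' @return A `chic_truncnb` object: list with `mu`, `size`,
#'   `truncation_point`, `loglik`, `threshold` (5% quantile of the
#'   untruncated fit, see [interactability_threshold()]), `n_fitted`,
#'   `converged`.
#' @export
fit_truncated_nb <- function(n_trans, t = 0, reltol = 1e-8) {
  x <- n_trans[n_trans >= t]
  if (length(x) < 30) {
    stop("need at least 30 observations at or above the truncation point")
  }
  if (length(unique(x)) == 1) {
    stop("degenerate data: all retained observations equal")
  }
  m <- mean(x)
  v <- var(x)
  size0 <- if (v > m) m^2 / (v - m) else 100
  size0 <- min(max(size0, 1e-3), 1e4)
  negll <- function(par) {
    mu <- exp(par[1])
    size <- exp(par[2])
    tail <- if (t > 0) {
      pnbinom(t - 1, mu = mu, size = size, lower.tail = FALSE, log.p = TRUE)
    } else 0
    ll <- sum(dnbinom(x, mu = mu, size = size, log = TRUE)) - length(x) * tail
    if (!is.finite(ll)) ll <- -1e12
    -ll
  }
  starts <- list(c(log(m), log(size0)),
                 c(log(2 * m), log(size0)),
                 c(log(m / 2), log(size0)))
  fits <- lapply(starts, function(p0) {
    tryCatch(
      stats::optim(p0, negll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 2000)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) stop("truncated NB fit failed from every start")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  if (best$convergence != 0) {
    stop("truncated NB fit did not converge; last iterate mu = ",
         signif(exp(best$par[1]), 4), ", size = ",
         signif(exp(best$par[2]), 4))
  }
  fit <- structure(
    list(mu = exp(best$par[1]), size = exp(best$par[2]),
         truncation_point = as.integer(t), loglik = -best$value,
         n_fitted = length(x), converged = TRUE),
    class = "chic_truncnb"
  )
  fit$threshold <- interactability_threshold(fit)
  fit
}

#' Interactability threshold from a truncated NB fit
#'
#' The smallest integer `q` whose cumulative probability under the
#' *untruncated* fitted negative binomial reaches 5% (CDF bracketing:
#' `CDF(q - 1) < 0.05 <= CDF(q)`). Fragments whose trans count falls below
#' `q` in any replicate are treated as failed baits.
#'
#' @param fit A `chic_truncnb` object (or any list with `mu` and `size`).
#' @param prob Quantile level; default 0.05.
#' @return Integer threshold `q`.
#' @export
interactability_threshold <- function(fit, prob = 0.05) {
  q <- qnbinom(prob, mu = fit$mu, size = fit$size)
  # guard the bracketing against quantile-function edge cases
  while (pnbinom(q, mu = fit$mu, size = fit$size) < prob) q <- q + 1
  while (q > 0 && pnbinom(q - 1, mu = fit$mu, size = fit$size) >= prob) {
    q <- q - 1
  }
  as.integer(q)
}

#' @export
print.chic_truncnb <- function(x, ...) {
  cat("Truncated negative-binomial interactability fit\n")
  cat(sprintf("  mu = %.3f, size = %.3f (t = %d, n = %d)\n",
              x$mu, x$size, x$truncation_point, x$n_fitted))
  cat(sprintf("  5%% threshold q = %d, logLik = %.2f\n",
              x$threshold, x$loglik))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chic_truncnb <- function(x, ...) {
  tibble::tibble(term = c("mu", "size"), estimate = c(x$mu, x$size))
}

#' @exportS3Method generics::glance
glance.chic_truncnb <- function(x, ...) {
  tibble::tibble(mu = x$mu, size = x$size,
                 truncation_point = x$truncation_point,
                 threshold = x$threshold, logLik = x$loglik,
                 n_fitted = x$n_fitted, converged = x$converged)
}

#' Fit per-replicate interactability filters for one cell line
#'
#' Runs truncation-point selection and the truncated NB fit for each
#' replicate of a cell line.
#'
#' @param trans_counts Tibble `frag_id`, `replicate_id`, `n_trans`
#'   (captured fragments only; see [compute_trans_counts()]).
#' @param method,manual_t,binwidth,window Passed to
#'   [select_truncation_point()]; `manual_t` may be a named vector keyed by
#'   replicate id.
#' @return Named list of `chic_truncnb` fits, one per replicate.
#' @export
fit_interactability_filters <- function(trans_counts,
                                        method = c("valley", "manual"),
                                        manual_t = NULL, binwidth = 1,
                                        window = 3) {
  method <- match.arg(method)
  reps <- sort(unique(trans_counts$replicate_id))
  fits <- lapply(reps, function(r) {
    x <- trans_counts$n_trans[trans_counts$replicate_id == r]
    t_r <- if (method == "manual") {
      if (!is.null(names(manual_t))) manual_t[[r]] else manual_t
    } else {
      select_truncation_point(x, method = "valley",
                              binwidth = binwidth, window = window)
    }
    fit_truncated_nb(x, t = t_r)
  })
  setNames(fits, reps)
}

#' Filter failed captured fragments on trans counts
#'
#' A captured fragment is kept only when its trans count reaches the
#' per-replicate 5% threshold in *every* replicate of the cell line; a
#' missing replicate count is treated as zero. Excluded fragments are
#' removed from all downstream peak calling for that cell line.
#'
#' @param trans_counts Tibble `frag_id`, `replicate_id`, `n_trans`.
#' @param fits Named list of `chic_truncnb` fits keyed by replicate id
#'   (see [fit_interactability_filters()]).
#' @return Tibble `frag_id`, one `n_trans_<rep>` column per replicate,
#'   `kept`.
#' @export
filter_fragments <- function(trans_counts, fits) {
  reps <- sort(unique(trans_counts$replicate_id))
  missing_fit <- setdiff(reps, names(fits))
  if (length(missing_fit) > 0) {
    stop("no interactability fit for replicate: ",
         paste(missing_fit, collapse = ", "))
  }
  thresholds <- purrr::map_int(fits[reps], "threshold")
  wide <- trans_counts |>
    tidyr::pivot_wider(id_cols = "frag_id", names_from = "replicate_id",
                       values_from = "n_trans", values_fill = 0L,
                       names_prefix = "n_trans_")
  pass <- purrr::map2(reps, thresholds, function(r, q) {
    wide[[paste0("n_trans_", r)]] >= q
  })
  wide$kept <- purrr::reduce(pass, `&`)
  wide
}

#' Serialize interactability fits and exclusion rates to a tidy report
#'
#' @param fits Named list of `chic_truncnb` fits keyed by replicate.
#' @param filter_result Output of [filter_fragments()].
#' @param cell_line Cell line label.
#' @return Tibble with one row per replicate: `cell_line`, `replicate_id`,
#'   `t`, `mu`, `size`, `threshold`, `n_fitted`, `pct_excluded` (cell-line
#'   level, repeated per row).
#' @export
interactability_report <- function(fits, filter_result, cell_line = "cell") {
  pct <- 100 * mean(!filter_result$kept)
  purrr::imap(fits, function(f, r) {
    tibble::tibble(cell_line = cell_line, replicate_id = r,
                   t = f$truncation_point, mu = f$mu, size = f$size,
                   threshold = f$threshold, n_fitted = f$n_fitted,
                   pct_excluded = pct)
  }) |>
    dplyr::bind_rows()
}
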