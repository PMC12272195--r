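#' Energy of a trait-loading series
#'
#' Overall dynamic activation of a trait for one subject: the sum of
#' squared loadings `sum(a^2)` across windows.
#'
#' @param a Numeric loading series.
#' @return Nonnegative scalar.
#' @export
trait_energy <- function(a) {
  sum(a^2)
}

#' Variation of a trait-loading series
#'
#' Mean absolute relative change of the loadings,
#' `mean(abs(diff(a)) / pmax(abs(head(a, -1)), eps))`. The denominator
#' guard `eps` keeps the metric defined when a loading crosses zero (a
#' warning is emitted when it triggers).
#'
#' @param a Numeric loading series of length `>= 2`.
#' @param eps Division guard.
#' @return Nonnegative scalar.
#' @export
trait_variation <- function(a, eps = 1e-8) {
  if (length(a) < 2) {
    abort("Variation needs at least two windows.",
      class = "dynalocus_invalid_input"
    )
  }
  denom <- abs(a[-length(a)])
  if (any(denom < eps)) {
    warn("Near-zero loading in variation denominator; guard applied.")
  }
  mean(abs(diff(a)) / pmax(denom, eps))
}

#' Lagged cross-correlation between two loading series
#'
#' For lag `k >= 0`,
#' `CCF_k = sum_{t=1}^{n-k} (x[t+k] - mean(x)) (y[t] - mean(y)) /
#'  (n * SD(x) * SD(y))`,
#' and the mirrored form for `k < 0`; means and SDs are full-series
#' population statistics, so `trait_ccf(x, x, 0) = 1`. By convention `x`
#' is the series of the more reproducible (higher-RI) trait of the pair.
#'
#' @param x,y Loading series of equal length.
#' @param k Integer lag, `|k| < length(x)`.
#' @return Correlation in `[-1, 1]`.
#' @export
trait_ccf <- function(x, y, k) {
  n <- length(x)
  if (length(y) != n) {
    abort("Series must have equal length.", class = "dynalocus_invalid_input")
  }
  if (abs(k) >= n) {
    abort("|k| must be smaller than the series length.",
      class = "dynalocus_invalid_input"
    )
  }
  mx <- mean(x)
  my <- mean(y)
  sdx <- sqrt(mean((x - mx)^2))
  sdy <- sqrt(mean((y - my)^2))
  if (sdx == 0 || sdy == 0) {
    warn("Zero-variance loading series; CCF set to 0.")
    return(0)
  }
  if (k >= 0) {
    idx <- seq_len(n - k)
    s <- sum((x[idx + k] - mx) * (y[idx] - my))
  } else {
    idx <- seq_len(n + k)
    s <- sum((x[idx] - mx) * (y[idx - k] - my))
  }
  s / (n * sdx * sdy)
}

#' Per-subject energy and variation of all trait loadings
#'
#' @param fit A `dlocus_fit`.
#' @param eps Division guard passed to [trait_variation()].
#' @return Tibble with columns `subject`, `trait`, `energy`, `variation`.
#' @export
trait_dynamics <- function(fit, eps = 1e-8) {
  q <- ncol(fit$A)
  out <- tidyr::expand_grid(
    subject = fit$subject_ids,
    trait = seq_len(q)
  )
  vals <- purrr::pmap(out, function(subject, trait) {
    i <- match(subject, fit$subject_ids)
    a <- fit$A[(i - 1) * fit$T + seq_len(fit$T), trait]
    tibble::tibble(energy = trait_energy(a), variation = trait_variation(a, eps))
  })
  dplyr::bind_cols(out, dplyr::bind_rows(vals))
}

#' Peak synchronization between a pair of traits across subjects
#'
#' For each subject, finds the lag in `-max_lag..max_lag` at which the
#' absolute CCF between the pair's loading series peaks (ties: smaller
#' `|k|`, then the negative lag first), then summarizes across the cohort:
#' the population lag is the mode of the per-subject peak lags (ties
#' toward smaller `|lag|`, negative first) and `median_ccf` is the median
#' of the signed CCF values at each subject's own peak lag. The pair
#' should be ordered `(higher-RI trait, lower-RI trait)`.
#'
#' @param fit A `dlocus_fit`.
#' @param pair Length-2 integer vector of trait indices `(l, l2)`.
#' @param max_lag Maximum lag searched.
#' @return List with `pair`, `per_subject` (tibble: subject, lag, ccf),
#'   `lag` (population mode), and `median_ccf`.
#' @export
trait_sync <- function(fit, pair, max_lag = 5L) {
  stopifnot(length(pair) == 2)
  lags <- seq(-max_lag, max_lag)
  # candidate order for tie-breaks: |k| ascending, negative before positive
  cand <- lags[order(abs(lags), lags)]
  per <- purrr::map(seq_len(fit$N), function(i) {
    rows <- (i - 1) * fit$T + seq_len(fit$T)
    x <- fit$A[rows, pair[1]]
    y <- fit$A[rows, pair[2]]
    cc <- vapply(cand, function(k) trait_ccf(x, y, k), numeric(1))
    best <- which.max(abs(cc)) # first in tie-break order wins
    tibble::tibble(
      subject = fit$subject_ids[i], lag = cand[best], ccf = cc[best]
    )
  })
  per <- dplyr::bind_rows(per)
  tab <- table(per$lag)
  modes <- as.integer(names(tab)[tab == max(tab)])
  lag_pop <- modes[order(abs(modes), modes)][1]
  list(
    pair = pair,
    per_subject = per,
    lag = lag_pop,
    median_ccf = median(per$ccf)
  )
}

#' Screen all trait pairs for strong synchronization
#'
#' Computes [trait_sync()] for every trait pair (ordered by reliability if
#' `ri` is given) and flags pairs whose median absolute CCF exceeds
#' `threshold`.
#'
#' @param fit A `dlocus_fit`.
#' @param ri Optional per-trait reliability indices used to order each
#'   pair as (higher-RI, lower-RI); default keeps index order.
#' @param max_lag Maximum lag searched.
#' @param threshold Strong-synchronization screen on `|median_ccf|`.
#' @return Tibble with `trait_x`, `trait_y`, `lag`, `median_ccf`,
#'   `strong`.
#' @export
trait_sync_table <- function(fit, ri = NULL, max_lag = 5L,
                             threshold = 0.35) {
  q <- ncol(fit$A)
  pairs <- utils::combn(q, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    if (!is.null(ri) && ri[pr[2]] > ri[pr[1]]) pr <- rev(pr)
    sy <- trait_sync(fit, pr, max_lag)
    tibble::tibble(
      trait_x = pr[1], trait_y = pr[2], lag = sy$lag,
      median_ccf = sy$median_ccf,
      strong = abs(sy$median_ccf) > threshold
    )
  })
  dplyr::bind_rows(rows)
}
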