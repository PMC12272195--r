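#' BIC-type criterion for a fitted decomposition
#'
#' Evaluates, on the reduced (whitened) data, minus twice the Gaussian
#' log-likelihood of the `q` rows of `y_tilde` around their model
#' reconstruction `A_tilde %*% S` with per-entry variance
#' `sigma2 = sum((y_tilde - A_tilde S)^2) / (q * p)`, plus the sparsity
#' penalty `log(N) * sum_j ||s_j||_0`, where the L0 norm counts trait
#' entries exceeding `zero_tol` in magnitude and `N` is the number of
#' subjects. Smaller is better; the criterion trades likelihood against
#' the number of retained connections.
#'
#' @param fit A `dlocus_fit`.
#' @param zero_tol Magnitude below which a trait entry counts as zero.
#' @return One-row tibble with `phi`, `rho`, `bic`, `l0_total`,
#'   `sigma_tilde_sq`.
#' @export
dlocus_bic <- function(fit, zero_tol = 1e-6) {
  Yt <- fit$whitened$y_tilde
  q <- nrow(Yt)
  p <- ncol(Yt)
  resid <- Yt - fit$A_tilde %*% fit$S
  rss <- sum(resid^2)
  sigma2 <- rss / (q * p)
  l0 <- sum(abs(fit$S) > zero_tol)
  if (sigma2 == 0) {
    warn("Zero residual variance; BIC likelihood is degenerate.")
    bic <- -Inf
  } else {
    minus2ll <- q * p * log(2 * pi * sigma2) + rss / sigma2
    bic <- minus2ll + log(fit$N) * l0
  }
  tibble::tibble(
    phi = fit$control$phi, rho = fit$control$rho, bic = bic,
    l0_total = l0, sigma_tilde_sq = sigma2
  )
}

#' Select the sparsity and rank-proportion parameters by BIC
#'
#' Fits the decomposition for every `(phi, rho)` pair on a shared seed and
#' returns the BIC-minimizing pair (ties broken toward smaller `phi`, then
#' smaller `rho`) together with the full grid table.
#'
#' @param stack A [dfc_stack()].
#' @param q Number of traits.
#' @param phi_values,rho_values Ascending grids.
#' @param lambda Smoothness parameter held fixed during the search.
#' @param seed Shared fit seed.
#' @param ... Further arguments passed to [dlocus()].
#' @return List with `phi`, `rho`, and `table` (tibble of BIC records;
#'   failed fits appear with `NA` BIC and are excluded from the argmin).
#' @export
select_phi_rho <- function(stack, q, phi_values, rho_values,
                           lambda = 0.01, seed = 1L, ...) {
  if (!length(phi_values) || !length(rho_values)) {
    abort("Grids must be non-empty.", class = "dynalocus_invalid_input")
  }
  grid <- tidyr::expand_grid(phi = sort(phi_values), rho = sort(rho_values))
  recs <- purrr::pmap(grid, function(phi, rho) {
    res <- tryCatch(
      dlocus_bic(dlocus(stack,
        q = q, phi = phi, lambda = lambda, rho = rho,
        seed = seed, ...
      )),
      error = function(e) {
        warn(sprintf(
          "Fit failed at phi = %g, rho = %g: %s", phi, rho,
          conditionMessage(e)
        ))
        tibble::tibble(
          phi = phi, rho = rho, bic = NA_real_,
          l0_total = NA_integer_, sigma_tilde_sq = NA_real_
        )
      }
    )
    res
  })
  table <- dplyr::bind_rows(recs)
  ok <- dplyr::filter(table, is.finite(.data$bic))
  if (!nrow(ok)) abort("All fits in the grid failed.")
  best <- dplyr::arrange(ok, .data$bic, .data$phi, .data$rho)[1, ]
  list(phi = best$phi, rho = best$rho, table = table)
}

#' Select the smoothness parameter by reconstruction error
#'
#' Computes the mean-squared reconstruction error
#' `norm(Y_c - A S, "F")^2 / (NT * p)` (with `A = H_star %*% A_tilde`) for
#' each candidate `lambda` and returns the largest `lambda` whose error is
#' within a factor `(1 + slack)` of the grid minimum — the most smoothing
#' the data tolerate without materially hurting goodness of fit.
#'
#' @param stack A [dfc_stack()].
#' @param q Number of traits.
#' @param phi,rho Sparsity and rank-proportion parameters (held fixed).
#' @param lambda_values Candidate grid.
#' @param slack Relative tolerance above the minimum error (default 1%).
#' @param seed Shared fit seed.
#' @param ... Further arguments passed to [dlocus()].
#' @return List with `lambda` and `table` (tibble of per-lambda errors).
#' @export
select_lambda <- function(stack, q, phi, rho, lambda_values,
                          slack = 0.01, seed = 1L, ...) {
  if (!length(lambda_values)) {
    abort("`lambda_values` must be non-empty.",
      class = "dynalocus_invalid_input"
    )
  }
  centered <- center_stack(stack)
  p <- ncol(stack$y)
  nt <- nrow(stack$y)
  errs <- vapply(sort(lambda_values), function(lam) {
    fit <- dlocus(stack,
      q = q, phi = phi, lambda = lam, rho = rho,
      seed = seed, ...
    )
    sum((centered$y_c - fit$A %*% fit$S)^2) / (nt * p)
  }, numeric(1))
  table <- tibble::tibble(lambda = sort(lambda_values), mse = errs)
  admissible <- table$mse <= (1 + slack) * min(table$mse)
  list(lambda = max(table$lambda[admissible]), table = table)
}
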