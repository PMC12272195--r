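#' Configuration for the synthetic dFC generator
#'
#' Defaults reproduce the recovery-study conditions: `V = 50` nodes,
#' `q = 8` traits, `T = 36` windows, block-structured sparse low-rank
#' sources with ~80% zero entries, smooth positive-mean AR(1) loadings,
#' and i.i.d. Gaussian noise whose SD takes the low / medium / high values
#' 0.5, 1.5, 2.5.
#'
#' @param V,q,N,T Problem dimensions (nodes, traits, subjects, windows).
#' @param sigma Noise SD.
#' @param ranks Optional per-trait ranks; default drawn uniformly in 1..3.
#' @param sparsity Target fraction of zero entries of the trait matrix
#'   `S` (enforced at the `S`-matrix level; block sizes are drawn to meet
#'   the implied per-trait nonzero budget and clamped to 5–15 nodes).
#' @param ar_coef Lag-1 autocorrelation of the loading series.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(V = 50L, q = 8L, N = 20L, T = 36L, sigma = 0.5,
                       ranks = NULL, sparsity = 0.8, ar_coef = 0.8,
                       seed = 1L) {
  stopifnot(V >= 5, q >= 1, N >= 1, T >= 2, sigma >= 0)
  if (ar_coef <= 0 || ar_coef >= 1) {
    abort("`ar_coef` must lie in (0, 1).", class = "dynalocus_invalid_input")
  }
  if (sparsity <= 0 || sparsity >= 1) {
    abort("`sparsity` must lie in (0, 1).", class = "dynalocus_invalid_input")
  }
  structure(
    list(
      V = as.integer(V), q = as.integer(q), N = as.integer(N),
      T = as.integer(T), sigma = sigma, ranks = ranks,
      sparsity = sparsity, ar_coef = ar_coef, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# One sparse low-rank trait: R latent vectors supported on contiguous
# node blocks, unit-normalized; scales with magnitude 1-3 and random
# signs. Block sizes are drawn around the per-block nonzero budget and
# clamped to 5..15 nodes.
draw_trait <- function(V, R, target_nnz) {
  per_block <- target_nnz / R
  b_center <- (1 + sqrt(1 + 8 * per_block)) / 2
  X <- matrix(0, V, R)
  for (r in seq_len(R)) {
    b <- round(b_center + sample(-2:2, 1))
    b <- max(5L, min(15L, min(V, as.integer(b))))
    start <- sample.int(V - b + 1L, 1)
    x <- numeric(V)
    x[start:(start + b - 1L)] <- rnorm(b)
    X[, r] <- x / sqrt(sum(x^2))
  }
  d <- runif(R, 1, 3) * sample(c(-1, 1), R, replace = TRUE)
  list(X = X, d = d, s = as.numeric(cpp_trait_signal(X, d)))
}

#' Generate sparse low-rank ground-truth traits
#'
#' Draws `q` block-structured traits with pairwise absolute correlations
#' below 0.3 (offending traits are redrawn, up to 100 attempts) and an
#' overall zero fraction of `S` within ±0.1 of the configured sparsity.
#'
#' @param cfg A [sim_config()]. Relies on the caller for seeding.
#' @return List with `S` (`q x p`), `X` (list), `d` (list), `ranks`.
#' @export
generate_sources <- function(cfg) {
  V <- cfg$V
  q <- cfg$q
  p <- V * (V - 1) / 2
  ranks <- cfg$ranks %||% sample(1:3, q, replace = TRUE)
  target_nnz <- (1 - cfg$sparsity) * p
  S <- matrix(0, q, p)
  X_list <- vector("list", q)
  d_list <- vector("list", q)
  attempts <- 0L
  l <- 1L
  while (l <= q) {
    tr <- draw_trait(V, ranks[l], target_nnz)
    ok <- TRUE
    if (l > 1L) {
      for (j in seq_len(l - 1L)) {
        if (abs(cor(tr$s, S[j, ])) >= 0.3) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      S[l, ] <- tr$s
      X_list[[l]] <- tr$X
      d_list[[l]] <- tr$d
      l <- l + 1L
    } else {
      attempts <- attempts + 1L
      if (attempts > 100L) {
        abort(
          paste(
            "Could not draw traits with pairwise |correlation| < 0.3;",
            "reduce q or the sparsity level."
          ),
          class = "dynalocus_sim_failure"
        )
      }
    }
  }
  list(S = S, X = X_list, d = d_list, ranks = ranks)
}

#' Generate smooth ground-truth loading series
#'
#' Per subject and trait, `a_t = mu + z_t` with `mu ~ N(1, 0.25)` and
#' `z_t` a stationary unit-variance AR(1) process with coefficient
#' `ar_coef`, so the lag-1 autocorrelation of the generated series equals
#' `ar_coef` in expectation.
#'
#' @param cfg A [sim_config()]. Relies on the caller for seeding.
#' @return `NT x q` loading matrix, rows subject-major.
#' @export
generate_loadings <- function(cfg) {
  N <- cfg$N
  T <- cfg$T
  q <- cfg$q
  ar <- cfg$ar_coef
  A <- matrix(0, N * T, q)
  for (i in seq_len(N)) {
    for (l in seq_len(q)) {
      mu <- rnorm(1, mean = 1, sd = 0.5)
      z <- numeric(T)
      z[1] <- rnorm(1)
      innov_sd <- sqrt(1 - ar^2)
      for (t in 2:T) z[t] <- ar * z[t - 1] + rnorm(1, sd = innov_sd)
      A[(i - 1) * T + seq_len(T), l] <- mu + z
    }
  }
  A
}

#' Generate a full synthetic dFC dataset
#'
#' Assembles `Y = A S + E` exactly, with the sources and loadings of
#' [generate_sources()] / [generate_loadings()] and i.i.d.
#' `N(0, sigma^2)` noise. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset`: list with `S_true`, `X_true`, `d_true`,
#'   `ranks`, `A_true`, `E`, `Y`, `stack` (a [dfc_stack()] view of `Y`),
#'   and `config`.
#' @export
sim_dlocus_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    src <- generate_sources(cfg)
    A <- generate_loadings(cfg)
    E <- matrix(
      rnorm(nrow(A) * ncol(src$S), sd = cfg$sigma),
      nrow(A), ncol(src$S)
    )
    Y <- A %*% src$S + E
    structure(
      list(
        S_true = src$S, X_true = src$X, d_true = src$d, ranks = src$ranks,
        A_true = A, E = E, Y = Y,
        stack = dfc_stack(Y, N = cfg$N, T = cfg$T, V = cfg$V),
        config = cfg
      ),
      class = "sim_dataset"
    )
  })
}

#' Recovery quality of a fit against simulation ground truth
#'
#' Greedy-matches estimated to true traits by absolute Pearson
#' correlation with sign alignment, then averages over traits (a) the
#' matched source correlations and (b) the correlations between true and
#' sign-aligned estimated loading columns under the same matching.
#'
#' @param sim A `sim_dataset`.
#' @param fit A `dlocus_fit` computed on `sim$stack` with `q` equal to
#'   the simulated trait count.
#' @return List with `source_cor` and `loading_cor`.
#' @export
evaluate_recovery <- function(sim, fit) {
  m <- greedy_match(sim$S_true, fit$S, h = "pearson")
  q <- nrow(sim$S_true)
  load_cor <- vapply(seq_len(q), function(l) {
    a_true <- sim$A_true[, l]
    a_est <- m$signs[l] * fit$A[, m$permutation[l]]
    if (sd(a_est) == 0) {
      warn("Matched loading column is constant; correlation set to 0.")
      return(0)
    }
    cor(a_true, a_est)
  }, numeric(1))
  list(
    source_cor = mean(m$similarities),
    loading_cor = mean(load_cor)
  )
}

#' Replicated recovery study over noise and sample-size settings
#'
#' For each `(N, sigma)` cell, generates `n_runs` seeded datasets, fits
#' the decomposition at fixed tuning parameters, and summarizes the mean
#' and SD of the matched source and loading correlations. Individual run
#' failures are excluded and counted.
#'
#' @param N_values,sigma_values Grid of sample sizes and noise SDs.
#' @param n_runs Replicate runs per cell.
#' @param V,q,T Problem dimensions.
#' @param phi,lambda,rho Tuning parameters used for every fit.
#' @param R_max,max_iter Fit budget for the study runs: rank cap (twice
#'   the generator's maximum true rank; on small-sample noisy data the
#'   similarity criterion would otherwise run ranks up to the
#'   uninformative noise floor) and sweep budget (the recovery metrics
#'   are stable well before full parameter convergence).
#' @param seed Base seed; run `r` of a cell uses a seed derived from it.
#' @param ... Further arguments passed to [dlocus()].
#' @return Tibble with one row per cell: `N`, `sigma`, `n_ok`,
#'   `n_failed`, `source_cor_mean`, `source_cor_sd`, `loading_cor_mean`,
#'   `loading_cor_sd`.
#' @export
run_recovery_study <- function(N_values = c(20L, 50L),
                               sigma_values = c(0.5, 1.5, 2.5),
                               n_runs = 20L, V = 50L, q = 8L, T = 36L,
                               phi = 1.5, lambda = 0.01, rho = 0.95,
                               R_max = 6L, max_iter = 40L,
                               seed = 1L, ...) {
  grid <- tidyr::expand_grid(N = N_values, sigma = sigma_values)
  cells <- purrr::pmap(grid, function(N, sigma) {
    res <- purrr::map(seq_len(n_runs), function(r) {
      run_seed <- derive_seed(seed, r + 1000L * (N + round(100 * sigma)))
      tryCatch(
        {
          sim <- sim_dlocus_data(sim_config(
            V = V, q = q, N = N, T = T,
            sigma = sigma, seed = run_seed
          ))
          fit <- dlocus(sim$stack,
            q = q, phi = phi, lambda = lambda,
            rho = rho, R_max = R_max, max_iter = max_iter,
            seed = run_seed, ...
          )
          evaluate_recovery(sim, fit)
        },
        error = function(e) {
          warn(sprintf(
            "Run %d failed at N = %d, sigma = %g: %s", r, N, sigma,
            conditionMessage(e)
          ))
          NULL
        }
      )
    })
    ok <- purrr::compact(res)
    src <- vapply(ok, `[[`, numeric(1), "source_cor")
    lod <- vapply(ok, `[[`, numeric(1), "loading_cor")
    tibble::tibble(
      N = N, sigma = sigma, n_ok = length(ok),
      n_failed = n_runs - length(ok),
      source_cor_mean = mean(src), source_cor_sd = sd(src),
      loading_cor_mean = mean(lod), loading_cor_sd = sd(lod)
    )
  })
  dplyr::bind_rows(cells)
}
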