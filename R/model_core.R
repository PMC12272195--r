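#' Fit the regularized dFC decomposition
#'
#' Decomposes a multi-subject dFC stack `Y` (`NT x p`) into `q` latent
#' connectivity traits `S` (`q x p`) and trait loadings `A` (`NT x q`)
#' with `Y ~ A S`. Each trait is modeled through a low-rank symmetric
#' factorization `s_l = L(X_l D_l X_l')` with unit-norm latent coordinate
#' columns and trait-specific rank `R_l` chosen adaptively; an angle-based
#' L1 penalty on the reconstructed edge values `x_l(u)' D_l x_l(v)`
#' induces element-wise sparsity in the traits, and a quadratic penalty on
#' within-subject adjacent-window loading differences enforces temporal
#' smoothness.
#'
#' After column-centering and SVD whitening to unit per-edge variance
#' (`y_tilde = H Y_c`, with dewhitening `H_star` and smoothness operator
#' `W = R_star H_star`; see [whiten_dfc()], `scale = "edge"`), the
#' objective minimized by block coordinate descent is
#'
#' \deqn{\| \tilde Y - \tilde A S \|_F^2
#'   + \phi \sum_l \sum_{u<v} | x_l(u)' D_l x_l(v) |
#'   + \lambda \| W \tilde A \|_F^2,}
#'
#' which coincides with the per-trait projection form
#' \eqn{\sum_l \|\tilde Y' \tilde a_l - s_l\|^2} when the reduced mixing
#' matrix is orthonormal (the configuration whitening induces). The
#' objective is block multiconvex: each node's latent coordinates and
#' each scale vector `d_l` are updated by exact convex minimization of a
#' penalized least-squares subproblem (warm-started ADMM), and the
#' mixing matrix by the analytic smoothness-penalized regression of the
#' reduced data on the sources (see [update_mixing()]). The objective
#' never increases across sweeps once trait ranks are frozen.
#'
#' @param stack A [dfc_stack()].
#' @param q Number of latent traits.
#' @param phi Sparsity tuning parameter (`>= 0`).
#' @param lambda Temporal smoothness tuning parameter (`>= 0`).
#' @param rho Rank-adaptation proportion in (0, 1): the rank `R_l` is the
#'   smallest integer whose low-rank truncation of the unconstrained trait
#'   estimate attains relative squared error `<= 1 - rho`.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @param tol Convergence tolerance on the maximum relative change of
#'   `(S, A_tilde)` between sweeps.
#' @param seed Integer seed controlling the stochastic initialization;
#'   fits are bit-reproducible given the seed.
#' @param R_max Cap on the per-trait rank (default `min(V - 1, 20)`).
#' @param rank_refresh_sweeps Number of initial sweeps during which trait
#'   ranks are re-selected from the unconstrained estimates; afterwards
#'   ranks are frozen so the descent is monotone.
#' @return A `dlocus_fit` object: list with `S` (`q x p`), `A` (`NT x q`),
#'   `A_tilde` (`q x q`), per-trait `X` and `d` lists, `ranks`, the
#'   `whitened` preprocessing operators, `column_means`, `objective_trace`,
#'   `n_iter`, `converged`, and the call parameters in `control`.
#' @export
#' @examples
#' sim <- sim_dlocus_data(sim_config(V = 15, q = 2, N = 3, T = 8, sigma = 0))
#' fit <- dlocus(sim$stack, q = 2, phi = 0.1, lambda = 0.01, seed = 1)
#' glance(fit)
dlocus <- function(stack, q, phi = 1.5, lambda = 0.01, rho = 0.95,
                   max_iter = 200L, tol = 1e-4, seed = 1L,
                   R_max = NULL, rank_refresh_sweeps = 5L) {
  stopifnot(inherits(stack, "dfc_stack"))
  if (phi < 0 || lambda < 0) {
    abort("`phi` and `lambda` must be nonnegative.",
      class = "dynalocus_invalid_input"
    )
  }
  if (rho <= 0 || rho >= 1) {
    abort("`rho` must lie in (0, 1).", class = "dynalocus_invalid_input")
  }
  N <- stack$N
  T <- stack$T
  V <- stack$V
  p <- ncol(stack$y)
  if (N * T < q) abort("Need NT >= q.", class = "dynalocus_invalid_input")
  R_max <- R_max %||% min(V - 1L, 20L)

  centered <- center_stack(stack)
  wh <- whiten_dfc(centered$y_c, q, scale = "edge")
  Yt <- wh$y_tilde
  W <- smoothness_operator_fast(wh$H_star, N, T)
  WtW <- crossprod(W)

  init <- init_decomposition(wh, q = q, rho = rho, R_max = R_max, seed = seed)
  X_list <- init$X
  d_list <- init$d
  S <- init$S
  A_tilde <- update_mixing(Yt, S, WtW, lambda, A_tilde = t(init$rotation))

  obj_trace <- numeric(0)
  rel_trace <- numeric(0)
  obj_prev <- Inf
  n_bad <- 0L
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    S_old <- S
    A_old <- A_tilde
    YtA <- crossprod(Yt, A_tilde) # p x q, column l = Y~' a~_l
    G <- crossprod(A_tilde) # q x q Gram of the mixing columns
    for (l in seq_len(q)) {
      g_ll <- G[l, l]
      if (g_ll < 1e-12) next # dead trait: no identifiable update
      # exact block target: project the trait-l residual onto a~_l
      cross <- S * G[, l] # rows m scaled by a~_m' a~_l
      r_l <- (YtA[, l] - colSums(cross) + g_ll * S[l, ]) / g_ll
      phi_eff <- phi / g_ll
      if (iter <= rank_refresh_sweeps) {
        ar <- adapt_rank(r_l, V, rho, R_max)
        if (ar$R != ncol(X_list[[l]])) {
          X_list[[l]] <- ar$X
          d_list[[l]] <- ar$d
        }
      }
      upd <- cpp_update_trait(r_l, X_list[[l]], d_list[[l]], phi_eff)
      X_list[[l]] <- upd$X
      d_list[[l]] <- as.numeric(upd$d)
      S[l, ] <- cpp_trait_signal(upd$X, upd$d)
    }
    A_tilde <- update_mixing(Yt, S, WtW, lambda, A_tilde)

    obj <- dlocus_objective(Yt, W, S, A_tilde, phi, lambda)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) && obj > obj_prev * (1 + 1e-6)) {
      n_bad <- n_bad + 1L
      if (n_bad >= 3L) {
        abort("Objective diverged across three consecutive sweeps.",
          class = "dynalocus_optim_failure",
          trace_values = obj_trace
        )
      }
    } else {
      n_bad <- 0L
    }
    obj_prev <- obj

    rel <- max(
      max(abs(S - S_old)) / max(max(abs(S_old)), 1e-12),
      max(abs(A_tilde - A_old)) / max(max(abs(A_old)), 1e-12)
    )
    rel_trace <- c(rel_trace, rel)
    if (iter > rank_refresh_sweeps && rel < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      S = S,
      A = wh$H_star %*% A_tilde,
      A_tilde = A_tilde,
      X = X_list,
      d = d_list,
      ranks = vapply(X_list, ncol, integer(1)),
      whitened = wh,
      column_means = centered$column_means,
      N = N, T = T, V = V,
      subject_ids = stack$subject_ids,
      node_labels = stack$node_labels,
      objective_trace = obj_trace,
      rel_change_trace = rel_trace,
      n_iter = iter,
      converged = converged,
      control = list(
        q = q, phi = phi, lambda = lambda, rho = rho, seed = seed,
        max_iter = max_iter, tol = tol, R_max = R_max,
        rank_refresh_sweeps = rank_refresh_sweeps
      )
    ),
    class = "dlocus_fit"
  )
}

#' Evaluate the regularized decomposition objective
#'
#' The reconstruction term `norm(y_tilde - A_tilde %*% S, "F")^2` plus
#' the angle-based sparsity penalty plus the temporal smoothness penalty,
#' on the reduced (whitened) scale. When `A_tilde` is orthonormal the
#' reconstruction term equals the per-trait projection form
#' `sum_l norm(t(y_tilde) %*% a_l - s_l)^2` up to an additive constant.
#'
#' @param y_tilde Reduced data (`q x p`).
#' @param W Smoothness operator `R_star %*% H_star`.
#' @param S Trait matrix (`q x p`); its entries are the reconstructed edge
#'   values `x_l(u)' D_l x_l(v)`, so the sparsity penalty is
#'   `phi * sum(abs(S))`.
#' @param A_tilde Reduced mixing matrix (`q x q`).
#' @param phi,lambda Sparsity and smoothness tuning parameters.
#' @return Nonnegative scalar.
#' @export
dlocus_objective <- function(y_tilde, W, S, A_tilde, phi, lambda) {
  fit <- sum((y_tilde - A_tilde %*% S)^2)
  fit + phi * sum(abs(S)) + lambda * sum((W %*% A_tilde)^2)
}

#' Unconstrained trait estimate
#'
#' The minimizer `Y~' a~_l` of the trait-`l` fit term over a free
#' (unstructured) source vector; used as the target of the low-rank
#' projection in rank adaptation.
#'
#' @param y_tilde Reduced data (`q x p`).
#' @param A_tilde Reduced mixing matrix.
#' @param l Trait index.
#' @return `p`-vector.
#' @export
unconstrained_source <- function(y_tilde, A_tilde, l) {
  as.numeric(crossprod(y_tilde, A_tilde[, l]))
}

#' Adaptive rank selection for one trait
#'
#' Rebuilds the hollow symmetric matrix from the unconstrained trait
#' estimate, eigendecomposes it, and retains the smallest number `R` of
#' components (ordered by absolute eigenvalue) such that the half-
#' vectorized rank-`R` truncation attains relative squared error
#' `<= 1 - rho`, capped at `R_max`.
#'
#' @param s_star Unconstrained trait estimate (`p`-vector).
#' @param V Number of nodes.
#' @param rho Similarity proportion in (0, 1).
#' @param R_max Rank cap (`< V`).
#' @return List with `R`, `X` (`V x R`, unit-norm columns), `d`
#'   (eigenvalues), and the attained relative error `rel_err`.
#' @export
adapt_rank <- function(s_star, V, rho, R_max = min(V - 1L, 20L)) {
  nrm2 <- sum(s_star^2)
  if (nrm2 == 0) {
    warn("Zero unconstrained estimate; returning rank-1 null trait.")
    X <- matrix(0, V, 1)
    X[1, 1] <- 1
    return(list(R = 1L, X = X, d = 0, rel_err = 0))
  }
  M <- unvectorize(s_star, V)
  eig <- eigen(M, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  R_max <- min(R_max, V - 1L)
  for (R in seq_len(R_max)) {
    X <- vecs[, seq_len(R), drop = FALSE]
    d <- vals[seq_len(R)]
    s_hat <- cpp_trait_signal(X, d)
    rel_err <- sum((s_hat - s_star)^2) / nrm2
    if (rel_err <= 1 - rho) break
  }
  list(R = as.integer(R), X = X, d = d, rel_err = rel_err)
}

#' Analytic update of the reduced mixing matrix
#'
#' Exact block update of the mixing matrix under the blind-source-
#' separation scale convention that each mixing column has unit norm
#' (magnitude lives in the sources; whitening makes the mixing matrix
#' approximately orthonormal, and the unit-column constraint pins the
#' per-trait scale split so the sparsity penalty keeps its meaning).
#' Each column in turn solves, conditioning on the others,
#'
#' \deqn{\min_{\|a\|_2 = 1}
#'   \| E_l - a\, s_l \|_F^2 + \lambda\, a' W'W a,}
#'
#' with `E_l` the residual of the other traits — a trust-region-type
#' quadratic program on the unit sphere solved exactly through the
#' eigendecomposition of `W'W` and its secular equation. At
#' `lambda = 0` the solution is the normalized regression direction
#' `E_l %*% s_l / ||E_l %*% s_l||`.
#'
#' @param y_tilde Reduced data (`q x p`).
#' @param S Trait matrix (`q x p`).
#' @param WtW Gram matrix `t(W) %*% W` of the smoothness operator.
#' @param lambda Smoothness tuning parameter.
#' @param A_tilde Current mixing matrix (warm start / residual state).
#' @param n_pass Column sweeps over the mixing matrix.
#' @return `q x q` matrix with unit-norm columns.
#' @export
update_mixing <- function(y_tilde, S, WtW, lambda, A_tilde = NULL,
                          n_pass = 2L) {
  q <- nrow(y_tilde)
  if (is.null(A_tilde)) A_tilde <- diag(q)
  eg <- eigen(WtW, symmetric = TRUE)
  lam <- pmax(lambda * eg$values, 0)
  Q <- eg$vectors
  E <- y_tilde - A_tilde %*% S
  for (pass in seq_len(n_pass)) {
    for (l in seq_len(q)) {
      b <- sum(S[l, ]^2)
      E_l <- E + tcrossprod(A_tilde[, l], S[l, ]) # residual without trait l
      v <- E_l %*% S[l, ]
      g <- as.numeric(crossprod(Q, v))
      w <- unit_quad_min(b + lam, g)
      a_new <- as.numeric(Q %*% w)
      A_tilde[, l] <- a_new
      E <- E_l - tcrossprod(a_new, S[l, ])
    }
  }
  A_tilde
}

# Minimize sum(d * w^2) - 2 * sum(g * w) subject to ||w|| = 1 (d >= 0
# up to shift): the trust-region secular equation. Returns the global
# minimizer.
unit_quad_min <- function(d, g) {
  n <- length(d)
  if (sqrt(sum(g^2)) < 1e-300) {
    # no linear term: any minimal-eigenvalue direction
    w <- numeric(n)
    w[which.min(d)] <- 1
    return(w)
  }
  dmin <- min(d)
  f <- function(mu) sum(g^2 / (d + mu)^2)
  # seek the multiplier mu > -dmin with f(mu) = 1 (f is decreasing there)
  eps <- 1e-10 * max(1, abs(dmin))
  lo <- -dmin + eps
  if (f(lo) >= 1) {
    hi <- -dmin + sqrt(sum(g^2)) + 1
    while (f(hi) > 1) hi <- 2 * hi + abs(dmin) + 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 1) lo <- mid else hi <- mid
      if (hi - lo < 1e-15 * max(1, abs(hi))) break
    }
    w <- g / (d + (lo + hi) / 2)
    return(w / sqrt(sum(w^2)))
  }
  # hard case: g has (numerically) no component on the minimal
  # eigenspace; pad with a minimal-eigenvalue direction
  w <- ifelse(d - dmin > eps, g / (d - dmin), 0)
  deficit <- 1 - sum(w^2)
  j <- which.min(d)
  w[j] <- w[j] + sqrt(max(deficit, 0))
  w / sqrt(sum(w^2))
}

#' Initialize the decomposition
#'
#' Runs a seeded fixed-point ICA rotation of the whitened rows (falling
#' back to the whitened rows themselves if the rotation does not
#' converge), projects each initial source to low rank via [adapt_rank()],
#' and assembles the initial trait matrix. Deterministic given the seed.
#'
#' @param whitened A `whitened_dfc`.
#' @param q Number of traits.
#' @param rho,R_max Rank-adaptation parameters (see [adapt_rank()]).
#' @param seed Integer seed.
#' @return List with `X` (list of `V x R_l`), `d` (list), `S` (`q x p`),
#'   and the rotation matrix `rotation`.
#' @export
init_decomposition <- function(whitened, q, rho = 0.95,
                               R_max = NULL, seed = 1L) {
  Yt <- whitened$y_tilde
  p <- ncol(Yt)
  V <- as.integer(round((1 + sqrt(1 + 8 * p)) / 2))
  R_max <- R_max %||% min(V - 1L, 20L)
  O <- with_seed(seed, fastica_rotation(Yt))
  S0 <- O %*% Yt
  X_list <- vector("list", q)
  d_list <- vector("list", q)
  S <- matrix(0, q, p)
  for (l in seq_len(q)) {
    ar <- adapt_rank(S0[l, ], V, rho, R_max)
    X_list[[l]] <- ar$X
    d_list[[l]] <- ar$d
    S[l, ] <- cpp_trait_signal(ar$X, ar$d)
  }
  list(X = X_list, d = d_list, S = S, rotation = O)
}

# Fixed-point (FastICA-style) symmetric orthogonal rotation of the
# orthonormal rows of y_tilde, tanh contrast. Returns the identity if the
# iteration fails to converge. Relies on the caller for seeding.
fastica_rotation <- function(y_tilde, max_iter = 200L, tol = 1e-6) {
  q <- nrow(y_tilde)
  p <- ncol(y_tilde)
  # rescale so the "observations" (columns) have identity covariance,
  # whatever whitening scale convention the rows carry
  Z <- sqrt(p) * y_tilde / sqrt(rowSums(y_tilde^2))
  sym_orth <- function(Wm) {
    e <- eigen(Wm %*% t(Wm), symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    e$vectors %*% diag(1 / sqrt(vals), q) %*% t(e$vectors) %*% Wm
  }
  Wm <- sym_orth(matrix(rnorm(q * q), q, q))
  for (i in seq_len(max_iter)) {
    U <- Wm %*% Z
    G <- tanh(U)
    Wn <- G %*% t(Z) / p - diag(rowMeans(1 - G^2), q) %*% Wm
    Wn <- sym_orth(Wn)
    delta <- max(abs(1 - abs(rowSums(Wn * Wm))))
    Wm <- Wn
    if (delta < tol) {
      return(Wm)
    }
  }
  diag(q) # fallback: use the whitened rows directly
}

#' Node contribution index
#'
#' For trait `l`, the contribution of node `v` is the squared norm of its
#' latent coordinates scaled by the (normalized absolute) dimension
#' weights: `g_l(v) = sum_r |d_r| / sum(|d|) * X[v, r]^2`. Ranks the
#' nodes driving a trait.
#'
#' @param fit A `dlocus_fit`.
#' @param l Trait index.
#' @return Nonnegative `V`-vector.
#' @export
node_contribution <- function(fit, l) {
  X <- fit$X[[l]]
  d <- fit$d[[l]]
  tot <- sum(abs(d))
  if (tot == 0) {
    warn("Trait has all-zero scales; node contributions are zero.")
    return(rep(0, nrow(X)))
  }
  as.numeric(X^2 %*% (abs(d) / tot))
}

#' @export
print.dlocus_fit <- function(x, ...) {
  cat(sprintf(
    "<dlocus_fit> q = %d traits, %d subjects x %d windows, %d nodes\n",
    ncol(x$A), x$N, x$T, x$V
  ))
  cat(sprintf(
    "  ranks: %s | phi = %g, lambda = %g, rho = %g\n",
    paste(x$ranks, collapse = " "), x$control$phi, x$control$lambda,
    x$control$rho
  ))
  cat(sprintf(
    "  %d sweeps, %sconverged, objective %.6g\n",
    x$n_iter, if (x$converged) "" else "NOT ",
    x$objective_trace[length(x$objective_trace)]
  ))
  invisible(x)
}
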