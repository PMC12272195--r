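test_that("objective matches a brute-force triple-sum evaluation", {
  set.seed(9)
  V <- 5
  q <- 2
  p <- V * (V - 1) / 2
  y_tilde <- matrix(rnorm(q * p), q, p)
  W <- matrix(rnorm(4 * q), 4, q)
  X_list <- list(
    qr.Q(qr(matrix(rnorm(V * 2), V, 2))),
    qr.Q(qr(matrix(rnorm(V * 2), V, 2)))
  )
  d_list <- list(c(1.5, -0.7), c(2, 0.3))
  A_tilde <- matrix(rnorm(q * q), q, q)
  S <- rbind(
    as.numeric(dynalocus:::cpp_trait_signal(X_list[[1]], d_list[[1]])),
    as.numeric(dynalocus:::cpp_trait_signal(X_list[[2]], d_list[[2]]))
  )
  expect_equal(
    dlocus_objective(y_tilde, W, S, A_tilde, phi = 0.7, lambda = 0.3),
    objective_brute(y_tilde, W, X_list, d_list, A_tilde, 0.7, 0.3),
    tolerance = 1e-10
  )

  # exact generating model, no penalties -> 0
  expect_equal(
    dlocus_objective(A_tilde %*% S, W, S, A_tilde, 0, 0), 0,
    tolerance = 1e-18
  )
  # phi = lambda = 0 -> plain least-squares term
  expect_equal(
    dlocus_objective(y_tilde, W, S, A_tilde, 0, 0),
    sum((y_tilde - A_tilde %*% S)^2)
  )
})

test_that("unconstrained source is the projection minimizer", {
  set.seed(10)
  q <- 3
  p <- 15
  y_tilde <- matrix(rnorm(q * p), q, p)
  A_tilde <- diag(q)
  expect_equal(unconstrained_source(y_tilde, A_tilde, 1), y_tilde[1, ])
  expect_equal(unconstrained_source(0 * y_tilde, A_tilde, 2), rep(0, p))

  # gradient check: ||Y~' a - s||^2 is minimized at s = Y~' a
  a <- rnorm(q)
  A2 <- cbind(a, matrix(rnorm(q * (q - 1)), q))
  s_star <- unconstrained_source(y_tilde, A2, 1)
  f <- function(s) sum((crossprod(y_tilde, a) - s)^2)
  for (i in 1:5) {
    expect_gte(f(s_star + rnorm(p, sd = 0.1)), f(s_star))
  }
})

test_that("adaptive rank selection matches an exhaustive scan of the criterion", {
  set.seed(11)
  V <- 12
  # rank-1 construction: single unit vector
  x <- rnorm(V)
  x <- x / sqrt(sum(x^2))
  s1 <- half_vectorize(2 * tcrossprod(x))
  ar <- adapt_rank(s1, V, rho = 0.5)
  expect_equal(ar$R, 1L)
  expect_lte(ar$rel_err, 0.5)

  # exhaustive-scan oracle on a random target at rho = 0.95
  s_star <- rnorm(V * (V - 1) / 2)
  R_max <- 8L
  errs <- vapply(seq_len(R_max), function(R) {
    M <- unvectorize(s_star, V)
    e <- eigen(M, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)[seq_len(R)]
    Xr <- e$vectors[, ord, drop = FALSE]
    recon <- Xr %*% (t(Xr) * e$values[ord])
    diag(recon) <- 0
    sum((half_vectorize(recon) - s_star)^2) / sum(s_star^2)
  }, numeric(1))
  brute <- which(errs <= 1 - 0.95)[1]
  if (is.na(brute)) brute <- R_max
  ar2 <- adapt_rank(s_star, V, rho = 0.95, R_max = R_max)
  expect_equal(ar2$R, as.integer(brute))

  # rho -> 0+ always selects rank 1
  expect_equal(adapt_rank(s_star, V, rho = 1e-9)$R, 1L)

  # zero target: guarded rank-1 null trait with a warning
  expect_warning(ar0 <- adapt_rank(rep(0, 66), 12, 0.9), "Zero")
  expect_equal(ar0$R, 1L)
  expect_equal(ar0$d, 0)

  # unit-norm columns
  expect_equal(colSums(ar2$X^2), rep(1, ar2$R), tolerance = 1e-10)
})

test_that("node and scale block updates solve their convex subproblems", {
  set.seed(12)
  # phi = 0: matches the normal-equations solution
  m <- 9
  R <- 3
  M <- matrix(rnorm(m * R), m, R)
  r <- rnorm(m)
  b <- as.numeric(dynalocus:::cpp_penalized_ls(M, r, 0, rep(0, R)))
  expect_equal(b, solve(crossprod(M), crossprod(M, r))[, 1], tolerance = 1e-8)

  # phi large: all fitted edge values shrink to zero
  b_inf <- dynalocus:::cpp_penalized_ls(M, r, 1e6, rnorm(R))
  expect_lt(max(abs(M %*% b_inf)), 1e-6)

  # random-search oracle: the solver beats thousands of candidates
  obj <- function(b, phi) sum((r - M %*% b)^2) + phi * sum(abs(M %*% b))
  for (phi in c(0.3, 1.5)) {
    b_hat <- dynalocus:::cpp_penalized_ls(M, r, phi, rep(0, R))
    cand <- matrix(rnorm(10000 * R, sd = 1), 10000, R)
    cand_obj <- apply(cand, 1, obj, phi = phi)
    expect_lte(obj(b_hat, phi), min(cand_obj) + 1e-10)
  }

  # duality-gap accuracy against a high-precision BFGS polish
  for (i in 1:3) {
    phi <- runif(1, 0.2, 2)
    b_hat <- dynalocus:::cpp_penalized_ls(M, r, phi, rep(0, R))
    o <- optim(b_hat, obj,
      phi = phi, method = "BFGS",
      control = list(maxit = 5000, reltol = 1e-15)
    )
    expect_lte(obj(b_hat, phi), o$value + 1e-6)
  }

  # rank-deficient phi = 0: minimum-norm among minimizers
  Md <- cbind(M[, 1], M[, 1], M[, 2])
  bd <- dynalocus:::cpp_penalized_ls(Md, r, 0, rep(0, 3))
  expect_equal(Md %*% bd, Md %*% MASS::ginv(Md) %*% r, tolerance = 1e-6)
  expect_lte(sum(bd^2), sum((MASS::ginv(Md) %*% r)^2) + 1e-8)
})

test_that("scale update design matrix matches the outer-product definition", {
  set.seed(13)
  V <- 6
  R <- 2
  X <- matrix(rnorm(V * R), V, R)
  Phi <- dynalocus:::cpp_scale_design(X)
  k <- 0
  for (u in 1:(V - 1)) {
    for (v in (u + 1):V) {
      k <- k + 1
      expect_equal(Phi[k, ], X[u, ] * X[v, ])
    }
  }
  d <- c(1.2, -0.4)
  expect_equal(
    as.numeric(dynalocus:::cpp_trait_signal(X, d)),
    half_vectorize(X %*% diag(d) %*% t(X) -
      diag(diag(X %*% diag(d) %*% t(X))))
  )
})

test_that("mixing update solves the constrained smoothness-penalized problem", {
  set.seed(14)
  q <- 3
  p <- 30
  y_tilde <- matrix(rnorm(q * p), q, p)
  S <- matrix(rnorm(q * p), q, p)
  W <- matrix(rnorm(8 * q), 8, q)
  WtW <- crossprod(W)

  for (lambda in c(0, 0.05, 1)) {
    # iterate the column Gauss-Seidel to a joint fixed point, then check
    A <- NULL
    for (it in 1:300) {
      A_new <- update_mixing(y_tilde, S, WtW, lambda, A, n_pass = 1)
      if (!is.null(A) && max(abs(A_new - A)) < 1e-13) {
        A <- A_new
        break
      }
      A <- A_new
    }
    expect_equal(colSums(A^2), rep(1, q), tolerance = 1e-10)
    fobj <- function(Avec) {
      Am <- matrix(Avec, q, q)
      Am <- sweep(Am, 2, sqrt(colSums(Am^2)), "/")
      sum((y_tilde - Am %*% S)^2) + lambda * sum((W %*% Am)^2)
    }
    # numeric-optimizer oracle on the normalized parametrization
    o <- optim(as.numeric(A), fobj,
      method = "BFGS",
      control = list(maxit = 2000, reltol = 1e-14)
    )
    expect_lte(fobj(as.numeric(A)), o$value + 1e-6)
    # per-column KKT: residual gradient is parallel to the column
    for (l in seq_len(q)) {
      E_l <- y_tilde - A[, -l, drop = FALSE] %*% S[-l, , drop = FALSE]
      grad <- (sum(S[l, ]^2) * diag(q) + lambda * WtW) %*% A[, l] -
        E_l %*% S[l, ]
      cross <- grad - sum(grad * A[, l]) * A[, l]
      expect_lt(sqrt(sum(cross^2)), 1e-7 * max(1, sqrt(sum(grad^2))))
    }
  }

  # heavy smoothing drives dewhitened loadings toward constancy in time
  N <- 2
  T <- 6
  H_star <- matrix(rnorm(N * T * q), N * T, q)
  Wr <- smoothness_operator(temporal_contrast(N, T), H_star)
  A_smooth <- update_mixing(y_tilde, S, crossprod(Wr), 1e8, n_pass = 8)
  A_rough <- update_mixing(y_tilde, S, crossprod(Wr), 0, n_pass = 8)
  expect_lt(
    sum((Wr %*% A_smooth)^2),
    sum((Wr %*% A_rough)^2) + 1e-8
  )
})

test_that("fits are deterministic, monotone, and recover noiseless structure", {
  tf <- tiny_fit()
  fit <- tf$fit
  sim <- tf$sim

  # noiseless recovery
  rec <- evaluate_recovery(sim, fit)
  expect_gt(rec$source_cor, 0.99)
  expect_gt(rec$loading_cor, 0.99)

  # objective trace non-increasing (within relative tolerance)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)])))

  # determinism: same data and seed give identical results
  fit2 <- dlocus(sim$stack, q = 3, phi = 0.1, lambda = 0.01, seed = 1)
  expect_equal(fit$S, fit2$S, tolerance = 1e-12)
  expect_equal(fit$A, fit2$A, tolerance = 1e-12)
  expect_equal(fit$objective_trace, fit2$objective_trace, tolerance = 1e-12)

  # structure invariants
  expect_equal(fit$A, fit$whitened$H_star %*% fit$A_tilde, tolerance = 1e-10)
  for (l in 1:3) {
    expect_equal(colSums(fit$X[[l]]^2), rep(1, fit$ranks[l]),
      tolerance = 1e-8
    )
    expect_equal(fit$S[l, ],
      as.numeric(dynalocus:::cpp_trait_signal(fit$X[[l]], fit$d[[l]])),
      tolerance = 1e-10
    )
  }
})

test_that("sparsity of the fitted traits is monotone in phi", {
  sim <- sim_dlocus_data(sim_config(
    V = 15, q = 2, N = 4, T = 10,
    sigma = 0.3, seed = 4
  ))
  nnz <- vapply(c(0.05, 0.5, 3), function(phi) {
    fit <- suppressWarnings(dlocus(sim$stack,
      q = 2, phi = phi, lambda = 0.01,
      seed = 3, max_iter = 40
    ))
    sum(abs(fit$S) > 1e-6)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("node contributions scale latent coordinates by dimension weights", {
  tf <- tiny_fit()
  fit <- tf$fit
  g <- node_contribution(fit, 1)
  expect_length(g, fit$V)
  expect_true(all(g >= 0))
  # direct formula: sum_r |d_r|/sum|d| * X[v, r]^2
  dnorm_ <- abs(fit$d[[1]]) / sum(abs(fit$d[[1]]))
  expect_equal(g, as.numeric(fit$X[[1]]^2 %*% dnorm_))

  # single-dimension trait with known coordinates
  fit_toy <- fit
  fit_toy$X[[1]] <- matrix(c(0.5, sqrt(1 - 0.25), rep(0, fit$V - 2)), ncol = 1)
  fit_toy$d[[1]] <- 4
  g_toy <- node_contribution(fit_toy, 1)
  expect_equal(g_toy[1], 0.25)
  expect_equal(g_toy[3], 0)

  # permutation equivariance
  perm <- sample(fit$V)
  fit_perm <- fit
  fit_perm$X[[1]] <- fit$X[[1]][perm, , drop = FALSE]
  expect_equal(node_contribution(fit_perm, 1), g[perm])

  # all-zero scales: zero vector with warning
  fit_zero <- fit
  fit_zero$d[[1]] <- rep(0, fit$ranks[1])
  expect_warning(g0 <- node_contribution(fit_zero, 1), "all-zero")
  expect_equal(g0, rep(0, fit$V))
})
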