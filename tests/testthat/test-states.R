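test_that("exemplar subsampling draws per-subject blocks deterministically", {
  A <- matrix(seq_len(30 * 2), 30, 2)
  ex1 <- exemplar_subsample(A, N = 3, T = 10, per_subject = 4, seed = 2)
  ex2 <- exemplar_subsample(A, N = 3, T = 10, per_subject = 4, seed = 2)
  expect_identical(ex1, ex2)
  expect_equal(nrow(ex1), 12)
  # rows 1-4 of the draw come from subject 1's block, etc.
  expect_true(all(ex1[1:4, 1] %in% 1:10))
  expect_true(all(ex1[5:8, 1] %in% 11:20))

  # per_subject = T returns the full data in order
  exf <- exemplar_subsample(A, N = 3, T = 10, per_subject = 10, seed = 1)
  expect_equal(exf, A)

  expect_error(
    exemplar_subsample(A, 3, 10, per_subject = 11),
    class = "dynalocus_invalid_input"
  )
})

test_that("k-medians recovers planted clusters and handles edge cases", {
  set.seed(40)
  # two well-separated blobs in loading space
  n_half <- 60
  A <- rbind(
    matrix(rnorm(n_half * 3, mean = 0, sd = 0.3), n_half, 3),
    matrix(rnorm(n_half * 3, mean = 4, sd = 0.3), n_half, 3)
  )
  truth <- rep(1:2, each = n_half)
  cl <- cluster_loadings(A, k = 2, N = 4, T = 30, per_subject = 10,
    restarts = 20, seed = 3
  )
  agree <- max(
    mean(cl$assignment == truth),
    mean(cl$assignment == 3 - truth)
  )
  expect_gt(agree, 0.99)
  # centroids are coordinate-wise medians of their members
  for (j in 1:2) {
    expect_equal(
      cl$centroids[j, ],
      apply(A[cl$assignment == j, ], 2, median),
      tolerance = 1e-12
    )
  }

  # k = 1: global coordinate-wise median
  cl1 <- cluster_loadings(A, k = 1, N = 4, T = 30)
  expect_equal(cl1$centroids[1, ], apply(A, 2, median))

  # duplicated rows get identical assignments
  Adup <- rbind(A, A[1:5, ])
  cl2 <- cluster_loadings(Adup, k = 2, N = 5, T = 25, per_subject = 10,
    restarts = 10, seed = 3
  )
  expect_equal(cl2$assignment[nrow(A) + 1:5], cl2$assignment[1:5])
})

test_that("elbow criterion finds the planted number of clusters", {
  set.seed(41)
  centers <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  A <- do.call(rbind, lapply(1:3, function(j) {
    sweep(matrix(rnorm(80 * 2, sd = 0.4), 80, 2), 2, centers[j, ], "+")
  }))
  k <- elbow_k(A, k_range = 2:6, N = 8, T = 30, per_subject = 15,
    restarts = 15, seed = 4
  )
  expect_equal(as.integer(k), 3L)
  ratios <- attr(k, "ratios")
  expect_length(ratios, 5)
  expect_true(all(is.finite(ratios)))

  expect_error(
    elbow_k(A, k_range = 2:3, N = 8, T = 30),
    class = "dynalocus_invalid_input"
  )
})

test_that("state reconstruction maps centroids through the trait basis", {
  set.seed(42)
  V <- 10
  p <- V * (V - 1) / 2
  S <- matrix(rnorm(3 * p), 3, p)

  # unit centroid reproduces a single trait's connectivity matrix
  st <- reconstruct_states(diag(3), S, V, assignment = rep(1:3, c(5, 3, 2)))
  expect_equal(st$state_matrices[[1]], unvectorize(S[1, ], V))
  expect_equal(sum(st$occurrence$occurrence_pct), 100)
  expect_equal(st$occurrence$occurrence_pct, c(50, 30, 20))

  # pipeline equivariance: permuting traits with matching S rows and
  # centroid columns leaves state matrices unchanged
  perm <- c(2, 3, 1)
  C <- matrix(rnorm(6), 2, 3)
  st1 <- reconstruct_states(C, S, V)
  st2 <- reconstruct_states(C[, perm], S[perm, ], V)
  expect_equal(st1$state_matrices, st2$state_matrices)

  # sparsity inheritance: a state's support lies in the union of the
  # supports of traits with nonzero centroid weight
  S_sp <- S
  S_sp[, 1:20] <- 0
  st3 <- reconstruct_states(matrix(c(1, 0, 2), 1, 3), S_sp, V)
  expect_true(all(abs(st3$state_edges[1, 1:20]) < 1e-12))
})

test_that("two-state loading simulation is recovered end to end", {
  set.seed(43)
  V <- 12
  p <- V * (V - 1) / 2
  q <- 2
  S <- matrix(0, q, p)
  S[1, 1:20] <- rnorm(20)
  S[2, 30:55] <- rnorm(26)
  prof <- rbind(c(2, 0.2), c(0.2, 2)) # two loading profiles
  N <- 4
  T <- 20
  A <- matrix(0, N * T, q)
  truth <- integer(N * T)
  for (i in 1:N) {
    for (t in 1:T) {
      s_id <- 1 + (t > T / 2)
      truth[(i - 1) * T + t] <- s_id
      A[(i - 1) * T + t, ] <- prof[s_id, ] + rnorm(q, sd = 0.05)
    }
  }
  fit <- structure(
    list(A = A, S = S, N = N, T = T, V = V,
      subject_ids = as.character(1:N)
    ),
    class = "dlocus_fit"
  )
  st <- dfc_states(fit, k = 2, per_subject = 10, restarts = 20, seed = 5)
  agree <- max(
    mean(st$assignment == truth),
    mean(st$assignment == 3 - truth)
  )
  expect_gt(agree, 0.99)
  # reconstructed states correlate with the true mixtures
  true_states <- prof %*% S
  m <- greedy_match(true_states, st$state_edges)
  expect_true(all(m$similarities > 0.99))
  expect_equal(sum(st$occurrence$occurrence_pct), 100, tolerance = 1e-9)
})
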