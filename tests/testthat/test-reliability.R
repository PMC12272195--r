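test_that("bootstrap resampling draws whole subjects, deterministically", {
  set.seed(20)
  y <- matrix(rnorm(8 * 6), 8, 6)
  st <- dfc_stack(y, N = 4, T = 2, V = 4)

  b1 <- bootstrap_resample(st, b = 3, seed = 9)
  b2 <- bootstrap_resample(st, b = 3, seed = 9)
  expect_identical(b1$y, b2$y)
  expect_false(identical(
    b1$y,
    bootstrap_resample(st, b = 4, seed = 9)$y
  ))

  # every drawn subject contributes its full contiguous window block
  draw <- attr(b1, "draw")
  for (i in seq_along(draw)) {
    expect_equal(
      b1$y[(i - 1) * 2 + 1:2, ],
      y[(draw[i] - 1) * 2 + 1:2, ]
    )
  }

  expect_error(
    bootstrap_resample(dfc_stack(y[1:2, ], 1, 2, 4), 1),
    class = "dynalocus_invalid_input"
  )

  # subject inclusion frequency over resamples matches 1 - (3/4)^4
  incl <- mean(vapply(1:1000, function(b) {
    1 %in% attr(bootstrap_resample(st, b, seed = 1), "draw")
  }, logical(1)))
  p_th <- 1 - (3 / 4)^4
  expect_lt(abs(incl - p_th), 3 * sqrt(p_th * (1 - p_th) / 1000))
})

test_that("greedy matching recovers permutations, signs, and crossed pairs", {
  set.seed(21)
  q <- 4
  p <- 40
  S <- matrix(rnorm(q * p), q, p)

  m0 <- greedy_match(S, S)
  expect_equal(m0$permutation, 1:q)
  expect_equal(m0$similarities, rep(1, q), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  signs <- c(-1, 1, -1, 1)
  Sb <- diag(signs) %*% S[perm, ]
  m1 <- greedy_match(S, Sb)
  # ref trait perm[j] sits at boot row j with sign signs[j]
  expect_equal(m1$permutation[perm], 1:q)
  expect_equal(m1$signs[perm], signs)
  expect_equal(m1$similarities, rep(1, q), tolerance = 1e-12)

  # crossed similarities: greedy picks (1,2) then (2,1)
  base <- matrix(rnorm(2 * 200), 2, 200)
  noise <- function(r, x) r * x + sqrt(1 - r^2) * rnorm(length(x))
  S_ref <- base
  S_b <- rbind(noise(0.8, base[2, ]), noise(0.9, base[1, ]))
  m2 <- greedy_match(S_ref, S_b)
  expect_equal(m2$permutation, c(2, 1))

  # jaccard similarity on supports
  Sa <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  Sb2 <- rbind(c(1, 1, 1, 0), c(0, 0, 0, 1))
  mj <- greedy_match(Sa, Sb2, h = "jaccard")
  expect_equal(mj$similarities, c(2 / 3, 1 / 2))
})

test_that("reliability index reproduces the chance-corrected formula", {
  # hand-constructed similarity structure via synthetic trait vectors:
  # verify the arithmetic directly on the formula instead
  ri_formula <- function(matched, overall) (matched - overall) / (1 - matched)
  expect_equal(ri_formula(0.6, 0.2), 1.0)
  expect_equal(ri_formula(0.3, 0.3), 0)

  # end-to-end on constructed bootstrap sets with known correlations
  set.seed(22)
  p <- 2000
  S_ref <- matrix(rnorm(2 * p), 2, p)
  mk_boot <- function(r1, r2) {
    rbind(
      r1 * S_ref[1, ] + sqrt(1 - r1^2) * rnorm(p),
      r2 * S_ref[2, ] + sqrt(1 - r2^2) * rnorm(p)
    )
  }
  boots <- list(mk_boot(0.9, 0.5), mk_boot(0.9, 0.5), mk_boot(0.9, 0.5))
  tab <- reliability_index(S_ref, boots)
  expect_equal(nrow(tab), 2)
  # matched means near the construction correlations
  expect_equal(tab$matched_mean[1], 0.9, tolerance = 0.03)
  expect_equal(tab$matched_mean[2], 0.5, tolerance = 0.05)
  # RI agrees with the formula applied to its own components
  expect_equal(
    tab$ri,
    (tab$matched_mean - tab$overall_mean) / (1 - tab$matched_mean)
  )
  # trait 1 is more reliable than trait 2
  expect_gt(tab$ri[1], tab$ri[2])

  # invariance to trait reordering of the bootstrap fits
  boots_perm <- lapply(boots, function(b) b[c(2, 1), ])
  tab_perm <- reliability_index(S_ref, boots_perm)
  expect_equal(tab$ri, tab_perm$ri, tolerance = 1e-12)

  # perfect match: Inf sentinel, labeled almost perfect, warned
  suppressWarnings(expect_warning(
    tab_inf <- reliability_index(S_ref, list(S_ref)),
    "RI set to Inf"
  ))
  expect_true(all(is.infinite(tab_inf$ri)))
  expect_true(all(tab_inf$interpretation == "almost perfect"))
})

test_that("interpretation bands follow the kappa-style guideline", {
  ri <- c(-0.1, 0, 0.1, 0.25, 0.45, 0.7, 0.85, 1.2)
  expect_equal(
    dynalocus:::ri_interpretation(ri),
    c(
      "none", "none", "slight", "fair", "moderate", "substantial",
      "almost perfect", "almost perfect"
    )
  )
})

test_that("bootstrap reliability separates structure from a noise trait", {
  # small but real pipeline: fit q = 3 on data generated from 2 traits,
  # so one fitted component is noise; its RI must be the minimum
  sim <- sim_dlocus_data(sim_config(
    V = 15, q = 2, N = 8, T = 10,
    sigma = 0.3, seed = 31
  ))
  fit <- suppressWarnings(dlocus(sim$stack,
    q = 3, phi = 0.1, lambda = 0.01,
    seed = 5, max_iter = 60
  ))
  rel <- suppressWarnings(
    dlocus_reliability(sim$stack, fit, B = 6, seed = 17)
  )
  expect_equal(nrow(rel), 3)
  expect_true(all(is.finite(rel$ri)))
  # greedy-match the two true traits to fitted traits; the leftover
  # fitted component is the noise trait and must have the lowest RI
  simmat <- abs(cor(t(sim$S_true), t(fit$S))) # 2 x 3
  structural <- integer(0)
  work <- simmat
  for (step in 1:2) {
    idx <- which(work == max(work), arr.ind = TRUE)[1, ]
    structural <- c(structural, idx[2])
    work[idx[1], ] <- -Inf
    work[, idx[2]] <- -Inf
  }
  noise_trait <- setdiff(1:3, structural)
  expect_equal(which.min(rel$ri), noise_trait)
})
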