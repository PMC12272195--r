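#' Bootstrap-resample a dFC stack at the subject level
#'
#' Draws `N` subjects with replacement (each drawn subject contributes its
#' full block of `T` windows) under a seed derived deterministically from
#' `(seed, b)`.
#'
#' @param stack A [dfc_stack()] with at least two subjects.
#' @param b Bootstrap replicate index.
#' @param seed Base seed.
#' @return A resampled `dfc_stack` (attribute `"draw"` holds the drawn
#'   subject indices).
#' @export
bootstrap_resample <- function(stack, b, seed = 1L) {
  stopifnot(inherits(stack, "dfc_stack"))
  if (stack$N < 2) {
    abort("Bootstrap needs N >= 2 subjects.",
      class = "dynalocus_invalid_input"
    )
  }
  draw <- with_seed(
    derive_seed(seed, b),
    sample.int(stack$N, stack$N, replace = TRUE)
  )
  rows <- as.vector(vapply(
    draw, function(i) (i - 1L) * stack$T + seq_len(stack$T),
    integer(stack$T)
  ))
  out <- dfc_stack(stack$y[rows, , drop = FALSE],
    N = stack$N, T = stack$T, V = stack$V,
    subject_ids = stack$subject_ids[draw],
    node_labels = stack$node_labels
  )
  attr(out, "draw") <- draw
  out
}

# Similarity between two trait vectors under the chosen measure. For
# pearson the signed correlation is returned; jaccard compares supports
# |s| > zero_tol.
trait_similarity <- function(a, b, h = c("pearson", "jaccard"),
                             zero_tol = 1e-6) {
  h <- match.arg(h)
  if (h == "pearson") {
    if (sd(a) == 0 || sd(b) == 0) {
      warn("Zero-variance trait; similarity set to 0.")
      return(0)
    }
    cor(a, b)
  } else {
    sa <- abs(a) > zero_tol
    sb <- abs(b) > zero_tol
    un <- sum(sa | sb)
    if (un == 0) {
      warn("Both supports empty; Jaccard similarity set to 0.")
      return(0)
    }
    sum(sa & sb) / un
  }
}

#' Greedily match two sets of latent traits
#'
#' Repeatedly selects the (reference, candidate) pair with the largest
#' absolute similarity, records the sign (for Pearson), removes both, and
#' repeats until all traits are matched. Ties break toward the lowest
#' reference index, then the lowest candidate index.
#'
#' @param S_ref,S_b `q x p` trait matrices.
#' @param h Similarity measure: `"pearson"` (default) or `"jaccard"`.
#' @return List with `permutation` (for each reference trait, the matched
#'   candidate row), `signs` (`±1`), and `similarities` (matched `|h|`).
#' @export
greedy_match <- function(S_ref, S_b, h = c("pearson", "jaccard")) {
  h <- match.arg(h)
  if (!all(dim(S_ref) == dim(S_b))) {
    abort("Trait matrices must share dimensions.",
      class = "dynalocus_invalid_input"
    )
  }
  q <- nrow(S_ref)
  sim <- matrix(0, q, q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      sim[i, j] <- trait_similarity(S_ref[i, ], S_b[j, ], h)
    }
  }
  perm <- integer(q)
  signs <- integer(q)
  sims <- numeric(q)
  work <- abs(sim)
  for (step in seq_len(q)) {
    best <- which(work == max(work), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]
    j <- best[2]
    perm[i] <- j
    sims[i] <- abs(sim[i, j])
    signs[i] <- if (sim[i, j] < 0) -1L else 1L
    work[i, ] <- -Inf
    work[, j] <- -Inf
  }
  list(permutation = perm, signs = signs, similarities = sims)
}

#' Reliability index from a reference fit and bootstrap trait matrices
#'
#' Chance-corrected bootstrap reproducibility of each trait: with
#' `matched_mean` the average (over replicates) sign-aligned similarity of
#' a trait to its greedy-matched bootstrap counterpart and `overall_mean`
#' the average absolute similarity of the trait to *all* bootstrap traits,
#' `RI = (matched_mean - overall_mean) / (1 - matched_mean)`. The index is
#' interpreted with Cohen's-kappa-style bands: `<= 0` none, 0–0.20 slight,
#' 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1
#' almost perfect.
#'
#' @param S_ref Reference trait matrix (`q x p`).
#' @param S_boot List of `B` bootstrap trait matrices (`q x p` each).
#' @param h Similarity measure: `"pearson"` or `"jaccard"`.
#' @return Tibble with one row per trait: `trait`, `matched_mean`,
#'   `overall_mean`, `ri`, `interpretation`.
#' @export
reliability_index <- function(S_ref, S_boot, h = c("pearson", "jaccard")) {
  h <- match.arg(h)
  if (!length(S_boot)) {
    abort("Need at least one bootstrap replicate.",
      class = "dynalocus_invalid_input"
    )
  }
  q <- nrow(S_ref)
  B <- length(S_boot)
  matched <- matrix(0, B, q)
  overall <- matrix(0, B, q)
  for (b in seq_len(B)) {
    Sb <- S_boot[[b]]
    m <- greedy_match(S_ref, Sb, h)
    matched[b, ] <- m$similarities
    for (l in seq_len(q)) {
      overall[b, l] <- mean(vapply(
        seq_len(q),
        function(j) abs(trait_similarity(S_ref[l, ], Sb[j, ], h)),
        numeric(1)
      ))
    }
  }
  matched_mean <- colMeans(matched)
  overall_mean <- colMeans(overall)
  ri <- numeric(q)
  for (l in seq_len(q)) {
    if (matched_mean[l] >= 1 - 1e-9) {
      warn(sprintf(
        "Trait %d matched similarity is 1 within tolerance; RI set to Inf.",
        l
      ))
      ri[l] <- Inf
    } else {
      ri[l] <- (matched_mean[l] - overall_mean[l]) / (1 - matched_mean[l])
    }
  }
  tibble::tibble(
    trait = seq_len(q),
    matched_mean = matched_mean,
    overall_mean = overall_mean,
    ri = ri,
    interpretation = ri_interpretation(ri)
  )
}

ri_interpretation <- function(ri) {
  dplyr::case_when(
    ri <= 0 ~ "none",
    ri <= 0.20 ~ "slight",
    ri <= 0.40 ~ "fair",
    ri <= 0.60 ~ "moderate",
    ri <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Bootstrap reliability analysis of a fitted decomposition
#'
#' Refits the decomposition on `B` subject-level bootstrap resamples
#' (fresh initialization seeds; the reference solution is *not* used to
#' initialize, which would bias reproducibility upward) and computes the
#' per-trait reliability index.
#'
#' @param stack The [dfc_stack()] the reference fit was computed on.
#' @param fit The reference `dlocus_fit`.
#' @param B Number of bootstrap replicates.
#' @param h Similarity measure: `"pearson"` or `"jaccard"`.
#' @param seed Base seed for resampling and refits.
#' @return A `dlocus_reliability` tibble (see [reliability_index()]) with
#'   attribute `B`.
#' @export
dlocus_reliability <- function(stack, fit, B = 50L,
                               h = c("pearson", "jaccard"), seed = 1L) {
  h <- match.arg(h)
  ctl <- fit$control
  S_boot <- vector("list", B)
  for (b in seq_len(B)) {
    bs <- bootstrap_resample(stack, b, seed)
    bfit <- dlocus(bs,
      q = ctl$q, phi = ctl$phi, lambda = ctl$lambda, rho = ctl$rho,
      max_iter = ctl$max_iter, tol = ctl$tol,
      seed = derive_seed(seed, b + 500000L),
      R_max = ctl$R_max, rank_refresh_sweeps = ctl$rank_refresh_sweeps
    )
    S_boot[[b]] <- bfit$S
  }
  out <- reliability_index(fit$S, S_boot, h)
  attr(out, "B") <- B
  class(out) <- c("dlocus_reliability", class(out))
  out
}
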