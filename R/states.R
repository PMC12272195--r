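#' Per-subject exemplar subsampling of trait loadings
#'
#' Uniform without-replacement draw of `per_subject` loading rows from
#' each subject's block, used to initialize dFC-state clustering.
#'
#' @param A `NT x q` loading matrix (subject-major rows).
#' @param N,T Numbers of subjects and windows per subject.
#' @param per_subject Rows drawn per subject (`<= T`).
#' @param seed Integer seed.
#' @return `(N * per_subject) x q` matrix in subject order.
#' @export
exemplar_subsample <- function(A, N, T, per_subject = 20L, seed = 1L) {
  if (per_subject > T) {
    abort("`per_subject` cannot exceed the number of windows.",
      class = "dynalocus_invalid_input"
    )
  }
  rows <- with_seed(seed, unlist(lapply(seq_len(N), function(i) {
    (i - 1L) * T + sort(sample.int(T, per_subject))
  })))
  A[rows, , drop = FALSE]
}

# One k-medians run (city-block distance, coordinate-wise median
# centroids) from given initial centroids. Empty clusters are re-seeded
# at the point farthest (L1) from its current centroid.
kmedians_run <- function(X, centroids, max_iter = 100L) {
  k <- nrow(centroids)
  n <- nrow(X)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D <- l1_distances(X, centroids)
    assignment <- max.col(-D, ties.method = "first")
    if (all(assignment == assign_old)) break
    assign_old <- assignment
    for (j in seq_len(k)) {
      members <- which(assignment == j)
      if (!length(members)) {
        warn("Empty cluster; re-seeding at the farthest point.")
        dmin <- D[cbind(seq_len(n), assignment)]
        far <- which.max(dmin)
        centroids[j, ] <- X[far, ]
        assignment[far] <- j
        assign_old <- rep(0L, n) # force another pass
      } else {
        centroids[j, ] <- apply(X[members, , drop = FALSE], 2, median)
      }
    }
  }
  D <- l1_distances(X, centroids)
  assignment <- max.col(-D, ties.method = "first")
  cost <- sum(D[cbind(seq_len(n), assignment)])
  list(assignment = assignment, centroids = centroids, cost = cost)
}

l1_distances <- function(X, C) {
  out <- matrix(0, nrow(X), nrow(C))
  for (j in seq_len(nrow(C))) {
    out[, j] <- rowSums(abs(sweep(X, 2, C[j, ], "-")))
  }
  out
}

#' Cluster trait loadings into dFC states (two-stage k-medians)
#'
#' Stage 1 runs k-medians with city-block distance on per-subject
#' exemplars under `restarts` random initializations (distinct data rows
#' as seeds), keeping the lowest-cost solution; stage 2 initializes
#' full-data k-medians from those centroids and iterates until the
#' assignments stabilize. Centroids are coordinate-wise medians.
#'
#' @param A `NT x q` loading matrix.
#' @param k Number of states (`>= 2`; `k = 1` returns the global median).
#' @param N,T Numbers of subjects and windows per subject.
#' @param per_subject Exemplars per subject for stage 1.
#' @param restarts Random initializations for stage 1.
#' @param seed Integer seed.
#' @return List with `assignment` (length `NT`), `centroids` (`k x q`),
#'   and stage-2 `cost`.
#' @export
cluster_loadings <- function(A, k, N, T, per_subject = 20L,
                             restarts = 100L, seed = 1L) {
  if (k == 1L) {
    cen <- matrix(apply(A, 2, median), 1)
    return(list(
      assignment = rep(1L, nrow(A)), centroids = cen,
      cost = sum(abs(sweep(A, 2, cen[1, ], "-")))
    ))
  }
  ex <- exemplar_subsample(A, N, T, per_subject, seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(
      derive_seed(seed, r),
      ex[sample.int(nrow(ex), k), , drop = FALSE]
    )
    run <- kmedians_run(ex, init)
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  kmedians_run(A, best$centroids)
}

#' Elbow selection of the number of dFC states
#'
#' For each `k` in `k_range`, clusters the loadings and computes the
#' ratio of the mean within-cluster city-block distance to the assigned
#' centroid over the mean pairwise between-centroid distance; returns the
#' `k` of maximum discrete curvature (second difference) of the ratio
#' curve, ties toward smaller `k`.
#'
#' @param A `NT x q` loading matrix.
#' @param k_range Candidate state counts (at least 3 values).
#' @param N,T Numbers of subjects and windows per subject.
#' @param ... Passed to [cluster_loadings()].
#' @param seed Integer seed.
#' @return Selected `k` (attribute `"ratios"` holds the ratio curve).
#' @export
elbow_k <- function(A, k_range, N, T, seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) {
    abort("`k_range` needs at least 3 values.",
      class = "dynalocus_invalid_input"
    )
  }
  ratios <- vapply(k_range, function(k) {
    cl <- cluster_loadings(A, k, N, T, seed = seed, ...)
    D <- l1_distances(A, cl$centroids)
    within <- mean(D[cbind(seq_len(nrow(A)), cl$assignment)])
    between <- mean(l1_distances(cl$centroids, cl$centroids)[
      upper.tri(diag(k))
    ])
    within / between
  }, numeric(1))
  curv <- diff(diff(ratios)) # second difference at interior points
  k_sel <- k_range[which.max(curv) + 1L]
  structure(k_sel, ratios = stats::setNames(ratios, k_range))
}

#' Identify and reconstruct whole-brain dFC states
#'
#' Clusters the trait-loading rows into `k` states (two-stage k-medians
#' with exemplar initialization), then reconstructs each state's
#' whole-brain connectivity matrix by passing the centroid loadings back
#' through the trait basis: `state_j = unvectorize(centroid_j %*% S)`.
#'
#' @param fit A `dlocus_fit`.
#' @param k Number of states, or `"auto"` to select by [elbow_k()].
#' @param k_range Candidate counts when `k = "auto"`.
#' @param per_subject,restarts,seed Clustering options (see
#'   [cluster_loadings()]).
#' @return A `dlocus_states` object: list with `k`, `centroids`,
#'   `assignment`, `occurrence` (tibble of per-state percentages summing
#'   to 100), and `state_matrices` (list of hollow symmetric `V x V`
#'   matrices).
#' @export
dfc_states <- function(fit, k = "auto", k_range = 2:8, per_subject = 20L,
                       restarts = 100L, seed = 1L) {
  A <- fit$A
  if (identical(k, "auto")) {
    k <- as.integer(elbow_k(A, k_range, fit$N, fit$T,
      seed = seed,
      per_subject = per_subject, restarts = restarts
    ))
  }
  cl <- cluster_loadings(A, k, fit$N, fit$T,
    per_subject = per_subject,
    restarts = restarts, seed = seed
  )
  reconstruct_states(cl$centroids, fit$S, fit$V, cl$assignment)
}

#' Reconstruct state matrices from centroid loadings
#'
#' @param centroids `k x q` matrix of centroid trait loadings.
#' @param S `q x p` trait matrix.
#' @param V Number of nodes.
#' @param assignment Optional state labels for all `NT` rows, used for
#'   the occurrence percentages.
#' @return A `dlocus_states` object (see [dfc_states()]).
#' @export
reconstruct_states <- function(centroids, S, V, assignment = NULL) {
  k <- nrow(centroids)
  edge_profiles <- centroids %*% S # k x p
  mats <- lapply(seq_len(k), function(j) unvectorize(edge_profiles[j, ], V))
  occurrence <- if (!is.null(assignment)) {
    counts <- tabulate(assignment, nbins = k)
    tibble::tibble(
      state = seq_len(k), n = counts,
      occurrence_pct = 100 * counts / length(assignment)
    )
  } else {
    tibble::tibble(
      state = seq_len(k), n = NA_integer_, occurrence_pct = NA_real_
    )
  }
  structure(
    list(
      k = k, centroids = centroids, assignment = assignment,
      occurrence = occurrence, state_matrices = mats,
      state_edges = edge_profiles
    ),
    class = "dlocus_states"
  )
}

#' @export
print.dlocus_states <- function(x, ...) {
  cat(sprintf("<dlocus_states> %d whole-brain dFC states\n", x$k))
  print(x$occurrence)
  invisible(x)
}
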