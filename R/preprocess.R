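#' Column-center a dFC stack
#'
#' Removes the mean of each of the `p` edge columns across all `NT`
#' subject-windows (the group blind-source-separation convention: centering
#' acts on the connectivity columns, leaving the connectivity space of the
#' latent traits intact). The removed means are kept for reconstruction.
#'
#' @param stack A [dfc_stack()].
#' @return List with `y_c` (centered `NT x p` matrix) and `column_means`
#'   (`p`-vector).
#' @export
center_stack <- function(stack) {
  stopifnot(inherits(stack, "dfc_stack"))
  mu <- colMeans(stack$y)
  list(y_c = sweep(stack$y, 2, mu, "-"), column_means = mu)
}

#' Dimension reduction and whitening of centered dFC data
#'
#' Via the thin SVD `Y_c = U S V'`, forms the reduced data `y_tilde`
#' (`q x p`), the whitening map `H` and the dewhitening map `H_star`, so
#' that `H_star %*% y_tilde` is the best rank-`q` approximation of `Y_c`
#' under either scale convention:
#' * `scale = "unit"` (default): `y_tilde = V_q'`, rows orthonormal
#'   (`y_tilde %*% t(y_tilde) = I_q`), `H = S_q^{-1} U_q'`,
#'   `H_star = U_q S_q`.
#' * `scale = "edge"`: `y_tilde = sqrt(p) V_q'`, so each reduced row has
#'   unit mean square across the `p` edges
#'   (`y_tilde %*% t(y_tilde) = p I_q`, the ICA convention). This is the
#'   scale [dlocus()] fits on: the sparsity penalty is not scale
#'   invariant, and on this scale latent traits have unit per-edge
#'   variance, which makes the tuning parameters transferable across
#'   data sizes.
#'
#' The sign of each row of `y_tilde` is fixed so its largest-magnitude
#' entry is positive (reproducibility convention).
#'
#' @param y_c Centered `NT x p` matrix.
#' @param q Number of retained components; must not exceed the rank
#'   of `y_c`.
#' @param scale Scale convention, `"unit"` or `"edge"` (see above).
#' @return A `whitened_dfc`: list with `y_tilde` (`q x p`), `H`
#'   (`q x NT`), `H_star` (`NT x q`), singular values `d`, `q`, and
#'   `scale`.
#' @export
whiten_dfc <- function(y_c, q, scale = c("unit", "edge")) {
  scale <- match.arg(scale)
  y_c <- as.matrix(y_c)
  q <- as.integer(q)
  if (q < 1 || q > min(dim(y_c))) {
    abort("`q` must be between 1 and min(NT, p).",
      class = "dynalocus_invalid_input"
    )
  }
  sv <- svd(y_c, nu = q, nv = q)
  tol <- max(dim(y_c)) * .Machine$double.eps * sv$d[1]
  achieved_rank <- sum(sv$d > tol)
  if (achieved_rank < q) {
    abort(
      sprintf(
        "Data has numerical rank %d < q = %d; cannot whiten.",
        achieved_rank, q
      ),
      class = "dynalocus_degenerate_rank"
    )
  }
  U <- sv$u
  V <- sv$v
  dq <- sv$d[seq_len(q)]
  # sign convention: largest-|entry| of each component of V positive
  sgn <- vapply(seq_len(q), function(j) {
    v <- V[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  U <- sweep(U, 2, sgn, "*")
  V <- sweep(V, 2, sgn, "*")
  cc <- if (scale == "edge") sqrt(ncol(y_c)) else 1
  structure(
    list(
      y_tilde = cc * t(V),
      H = cc * sweep(t(U), 1, dq, "/"),
      H_star = sweep(U, 2, dq / cc, "*"),
      d = dq,
      q = q,
      scale = scale
    ),
    class = "whitened_dfc"
  )
}

#' Temporal contrast (first-difference) operator
#'
#' Builds the `N(T-1) x NT` block first-difference matrix: for each
#' subject `i` and window `t = 2..T` a row with `-1` at position
#' `(i, t-1)` and `+1` at `(i, t)`. No row spans a subject boundary, so
#' for any loading matrix `A` (`NT x q`),
#' `norm(R_star %*% A, "F")^2` equals the within-subject sum of squared
#' adjacent-window loading differences.
#'
#' @param N Number of subjects.
#' @param T Windows per subject (`T >= 2`).
#' @return Dense `N(T-1) x NT` matrix.
#' @export
temporal_contrast <- function(N, T) {
  if (T < 2) abort("`T` must be >= 2.", class = "dynalocus_invalid_input")
  R <- matrix(0, N * (T - 1), N * T)
  for (i in seq_len(N)) {
    for (t in 2:T) {
      row <- (i - 1) * (T - 1) + (t - 1)
      R[row, (i - 1) * T + t - 1] <- -1
      R[row, (i - 1) * T + t] <- 1
    }
  }
  R
}

#' Temporal smoothness operator on the reduced mixing matrix
#'
#' `W = R_star %*% H_star`. For a reduced mixing matrix `A_tilde` with
#' full loadings `A = H_star %*% A_tilde`, `norm(W %*% A_tilde, "F")^2`
#' equals the temporal smoothness penalty, i.e. the sum over subjects and
#' adjacent windows of squared loading differences.
#'
#' @param R_star Output of [temporal_contrast()].
#' @param H_star Dewhitening matrix (`NT x q`).
#' @return `N(T-1) x q` matrix.
#' @export
smoothness_operator <- function(R_star, H_star) {
  if (ncol(R_star) != nrow(H_star)) {
    abort("Shapes of `R_star` and `H_star` are incompatible.",
      class = "dynalocus_invalid_input"
    )
  }
  R_star %*% H_star
}

# Fast equivalent of smoothness_operator(temporal_contrast(N, T), H_star):
# within-subject adjacent-row differences of H_star.
smoothness_operator_fast <- function(H_star, N, T) {
  q <- ncol(H_star)
  W <- matrix(0, N * (T - 1), q)
  for (i in seq_len(N)) {
    rows <- (i - 1) * T + seq_len(T)
    W[(i - 1) * (T - 1) + seq_len(T - 1), ] <-
      H_star[rows[-1], , drop = FALSE] - H_star[rows[-T], , drop = FALSE]
  }
  W
}
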