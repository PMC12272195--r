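#' Half-vectorize a symmetric connectivity matrix
#'
#' Maps a symmetric `V x V` matrix to its `p = V(V-1)/2` upper-triangle
#' entries in fixed row-major order `(1,2), (1,3), ..., (V-1,V)`, discarding
#' the diagonal. This edge ordering is the package-wide convention: every
#' connectivity vector (dFC window, latent trait, reconstructed state) uses
#' it.
#'
#' @param M A square, symmetric numeric matrix.
#' @param tol Symmetry tolerance; entries of `M - t(M)` larger than this in
#'   absolute value raise an error.
#' @return Numeric vector of length `V(V-1)/2`.
#' @seealso [unvectorize()]
#' @export
#' @examples
#' M <- matrix(c(0, .2, -.1, .2, 0, .5, -.1, .5, 0), 3, 3)
#' half_vectorize(M) # 0.2 -0.1 0.5
half_vectorize <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort("`M` must be a square matrix.", class = "dynalocus_invalid_input")
  }
  if (max(abs(M - t(M))) > tol) {
    abort("`M` must be symmetric (within tolerance).",
      class = "dynalocus_invalid_input"
    )
  }
  tM <- t(M)
  tM[lower.tri(tM)]
}

#' Rebuild a hollow symmetric matrix from a connection vector
#'
#' Inverse of [half_vectorize()] up to the (discarded) diagonal, which is
#' set to zero.
#'
#' @param s Connection vector of length `V(V-1)/2`.
#' @param V Number of nodes.
#' @return A hollow (zero-diagonal) symmetric `V x V` matrix.
#' @export
unvectorize <- function(s, V) {
  p <- V * (V - 1) / 2
  if (length(s) != p) {
    abort(
      sprintf("`s` has length %d; expected V(V-1)/2 = %d.", length(s), p),
      class = "dynalocus_invalid_input"
    )
  }
  tmp <- matrix(0, V, V)
  tmp[lower.tri(tmp)] <- s
  tmp + t(tmp)
}

# V x V matrix whose (u, v) entry is the position of edge (u, v) in the
# row-major half-vectorization; diagonal is 0.
edge_index_matrix <- function(V) {
  unvectorize(seq_len(V * (V - 1) / 2), V)
}

#' Tapered sliding-window weights
#'
#' Builds the taper used for windowed correlation: a rectangle of length
#' `width_tr` convolved with a centered Gaussian kernel of standard
#' deviation `taper_sigma_tr` (kernel support `±ceiling(3*sigma)`). By
#' default the convolved taper is truncated back to its central `width_tr`
#' samples, so the effective window length equals the nominal width (a
#' 120-volume series with width 15 and step 1 then yields 106 windows);
#' `truncate = FALSE` returns the full convolution of length
#' `width_tr + 2*ceiling(3*sigma)`. Weights are renormalized to sum to 1
#' and are symmetric about the center.
#'
#' @param width_tr Window width in TRs (positive integer).
#' @param taper_sigma_tr Gaussian kernel SD in TRs; `0` gives a flat
#'   rectangular window.
#' @param truncate Truncate the convolved taper to length `width_tr`?
#' @return Nonnegative weight vector summing to 1.
#' @export
tapered_weights <- function(width_tr, taper_sigma_tr = 0, truncate = TRUE) {
  width_tr <- as.integer(width_tr)
  if (width_tr < 1) {
    abort("`width_tr` must be >= 1.", class = "dynalocus_invalid_input")
  }
  if (taper_sigma_tr < 0) {
    abort("`taper_sigma_tr` must be >= 0.", class = "dynalocus_invalid_input")
  }
  if (taper_sigma_tr == 0) {
    return(rep(1 / width_tr, width_tr))
  }
  K <- ceiling(3 * taper_sigma_tr)
  kern <- dnorm(seq(-K, K), sd = taper_sigma_tr)
  kern <- kern / sum(kern)
  rect <- rep(1, width_tr)
  # full discrete convolution, length width_tr + 2K
  w <- convolve(rect, rev(kern), type = "open")
  if (truncate) {
    w <- w[(K + 1):(K + width_tr)]
  }
  w / sum(w)
}

#' Sliding-window dynamic connectivity for one subject
#'
#' Slides a tapered window along an `nt x V` multivariate series and, in
#' each window, computes the weighted Pearson correlation between every
#' node pair (taper weights as observation weights), clips `r` to
#' `±clip`, applies the Fisher z transform `atanh(r)`, and half-vectorizes.
#'
#' @param data Numeric `nt x V` matrix (rows = time points, columns =
#'   nodes); no missing values.
#' @param width_tr,step_tr,taper_sigma_tr Window specification: width and
#'   step in TRs and Gaussian taper SD (see [tapered_weights()]).
#' @param clip Correlations are clipped to `±clip` before `atanh` so the
#'   Fisher z values stay finite.
#' @return A `T x p` matrix of Fisher-z connectivity vectors with
#'   `T = floor((nt - L)/step) + 1` windows (`L` the taper length), with
#'   attribute `"n_windows"`.
#' @export
sliding_window_dfc <- function(data, width_tr = 15L, step_tr = 1L,
                               taper_sigma_tr = 3, clip = 1 - 1e-6) {
  data <- as.matrix(data)
  if (anyNA(data) || !all(is.finite(data))) {
    abort("`data` must be finite with no missing values.",
      class = "dynalocus_invalid_input"
    )
  }
  nt <- nrow(data)
  V <- ncol(data)
  if (V < 3) abort("Need at least 3 nodes.", class = "dynalocus_invalid_input")
  if (step_tr < 1) abort("`step_tr` must be >= 1.", class = "dynalocus_invalid_input")
  w <- tapered_weights(width_tr, taper_sigma_tr)
  L <- length(w)
  if (nt < L) {
    abort(
      sprintf("Series length %d shorter than window length %d.", nt, L),
      class = "dynalocus_invalid_input"
    )
  }
  n_win <- floor((nt - L) / step_tr) + 1
  p <- V * (V - 1) / 2
  out <- matrix(0, n_win, p)
  warned <- FALSE
  for (t in seq_len(n_win)) {
    idx <- (t - 1) * step_tr + seq_len(L)
    Xw <- data[idx, , drop = FALSE]
    m <- colSums(Xw * w)
    Xc <- sweep(Xw, 2, m, "-")
    C <- crossprod(Xc, Xc * w)
    s <- sqrt(diag(C))
    zero_var <- s <= 0
    if (any(zero_var)) {
      if (!warned) {
        warn("Constant node within a window; emitting z = 0 for its edges.")
        warned <- TRUE
      }
      s[zero_var] <- 1
      C[zero_var, ] <- 0
      C[, zero_var] <- 0
    }
    R <- C / tcrossprod(s)
    diag(R) <- 1
    R <- pmin(pmax(R, -clip), clip)
    out[t, ] <- atanh(half_vectorize(R, tol = 1e-6))
  }
  attr(out, "n_windows") <- n_win
  out
}

#' Stack per-subject dFC matrices into a group dFC stack
#'
#' Assembles per-subject `T x p` Fisher-z connectivity matrices into the
#' `NT x p` group data matrix `Y`, rows ordered subject-major and
#' window-minor (subject 1 windows `1..T`, then subject 2, ...).
#'
#' @param mats List of per-subject `T x p` matrices (all sharing `T`
#'   and `p`), as from [sliding_window_dfc()].
#' @param V Number of nodes.
#' @param subject_ids Optional subject identifiers (default names of
#'   `mats` or `1..N`).
#' @param node_labels Optional character vector of node labels.
#' @return A `dfc_stack`: list with elements `y` (`NT x p`), `N`, `T`,
#'   `V`, `subject_ids`, `node_labels`.
#' @export
stack_subjects <- function(mats, V, subject_ids = NULL, node_labels = NULL) {
  if (!length(mats)) abort("`mats` is empty.", class = "dynalocus_invalid_input")
  Ts <- vapply(mats, nrow, integer(1))
  ps <- vapply(mats, ncol, integer(1))
  if (length(unique(Ts)) != 1L || length(unique(ps)) != 1L) {
    abort("All subjects must share the same number of windows and edges.",
      class = "dynalocus_invalid_input"
    )
  }
  if (ps[1] != V * (V - 1) / 2) {
    abort("Edge count does not match V(V-1)/2.",
      class = "dynalocus_invalid_input"
    )
  }
  if (is.null(subject_ids)) {
    subject_ids <- names(mats) %||% as.character(seq_along(mats))
  }
  dfc_stack(do.call(rbind, mats),
    N = length(mats), T = Ts[1], V = V,
    subject_ids = subject_ids, node_labels = node_labels
  )
}

#' Construct a dFC stack from a precomputed data matrix
#'
#' @param y `NT x p` numeric matrix of half-vectorized Fisher-z dFC, rows
#'   subject-major and window-minor.
#' @param N,T,V Numbers of subjects, windows per subject, and nodes.
#' @param subject_ids,node_labels Optional identifiers.
#' @return A `dfc_stack` object.
#' @export
dfc_stack <- function(y, N, T, V, subject_ids = NULL, node_labels = NULL) {
  y <- as.matrix(y)
  if (nrow(y) != N * T) {
    abort("`y` must have N*T rows.", class = "dynalocus_invalid_input")
  }
  if (ncol(y) != V * (V - 1) / 2) {
    abort("`y` must have V(V-1)/2 columns.", class = "dynalocus_invalid_input")
  }
  if (!all(is.finite(y))) {
    abort("`y` must be finite.", class = "dynalocus_invalid_input")
  }
  structure(
    list(
      y = y, N = as.integer(N), T = as.integer(T), V = as.integer(V),
      subject_ids = subject_ids %||% as.character(seq_len(N)),
      node_labels = node_labels
    ),
    class = "dfc_stack"
  )
}

#' @export
print.dfc_stack <- function(x, ...) {
  cat(sprintf(
    "<dfc_stack> %d subjects x %d windows, %d nodes (%d edges)\n",
    x$N, x$T, x$V, ncol(x$y)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
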