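# Small reusable fixtures; everything is generated in code.

with_seed_local <- function(seed, code) dynalocus:::with_seed(seed, code)

# A tiny noiseless simulated dataset and its fit, shared across tests.
tiny_sim <- function(seed = 2) {
  sim_dlocus_data(sim_config(
    V = 20, q = 3, N = 5, T = 12, sigma = 0,
    seed = seed
  ))
}

tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_sim()
      cache <<- list(
        sim = sim,
        fit = dlocus(sim$stack,
          q = 3, phi = 0.1, lambda = 0.01,
          seed = 1
        )
      )
    }
    cache
  }
})

# Brute-force evaluation of the decomposition objective by explicit sums.
objective_brute <- function(y_tilde, W, X_list, d_list, A_tilde, phi,
                            lambda) {
  q <- nrow(y_tilde)
  V <- nrow(X_list[[1]])
  S <- t(vapply(
    seq_len(q),
    function(l) {
      M <- X_list[[l]] %*% diag(d_list[[l]], length(d_list[[l]])) %*%
        t(X_list[[l]])
      half_vectorize(M)
    },
    numeric(ncol(y_tilde))
  ))
  fit <- sum((y_tilde - A_tilde %*% S)^2)
  pen <- 0
  for (l in seq_len(q)) {
    M <- X_list[[l]] %*% diag(d_list[[l]], length(d_list[[l]])) %*%
      t(X_list[[l]])
    for (u in seq_len(V - 1)) {
      for (v in (u + 1):V) pen <- pen + abs(M[u, v])
    }
  }
  fit + phi * pen + lambda * sum((W %*% A_tilde)^2)
}
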