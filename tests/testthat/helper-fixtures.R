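# Shared fixture builders (all data is generated in code at test time).

# never let failing benchmark-reproduction checks truncate reporting of the
# remaining suite
options(testthat.progress.max_fails = 100L)

# small random indicator matrix with unit row structure
random_indicator <- function(t_length, m, seed) {
  set.seed(seed)
  x <- sample.int(m, t_length, replace = TRUE)
  encode_baseline(paste0("c", x), paste0("c", 1:m))
}

# a spec_matrix_estimate wrapping explicitly given real matrices
sme_from_matrices <- function(mats, freqs = NULL) {
  p <- nrow(mats[[1]])
  f_hat <- array(0i, dim = c(p, p, length(mats)))
  for (s in seq_along(mats)) f_hat[, , s] <- mats[[s]] + 0i
  if (is.null(freqs)) freqs <- seq_along(mats) / (2 * length(mats) + 1)
  structure(list(freqs = freqs,
                 f_hat = f_hat, bandwidth = 0L, weights = 1,
                 t_length = 2L * length(mats) + 1L),
            class = "spec_matrix_estimate")
}

# an envelope_scalings object from explicit lam / gam
feat_obj <- function(lam, gam) {
  structure(list(freqs = seq_along(lam) / (2 * length(lam) + 1),
                 lam = lam, gam = gam),
            class = "envelope_scalings")
}

# random PSD Hermitian matrix
random_hpsd <- function(p, seed) {
  set.seed(seed)
  a <- matrix(complex(real = rnorm(p * p), imaginary = rnorm(p * p)), p, p)
  a %*% Conj(t(a)) / p
}

# Brute-force maximization of the quadratic form a' M a over 1e5 random
# unit vectors: a uniform stage followed by refinement stages sampling
# around the incumbent. Independent of any eigendecomposition routine.
max_quad_random <- function(m_re, seed, n_total = 1e5) {
  set.seed(seed)
  p <- nrow(m_re)
  best_val <- -Inf
  best_vec <- NULL
  n_stage <- n_total / 5
  for (sigma in c(Inf, 0.3, 0.1, 0.03, 0.01)) {
    a <- matrix(rnorm(p * n_stage), nrow = p)
    if (is.finite(sigma)) a <- best_vec + sigma * a
    a <- sweep(a, 2, sqrt(colSums(a^2)), `/`)
    quad <- colSums(a * (m_re %*% a))
    if (max(quad) > best_val) {
      best_val <- max(quad)
      best_vec <- a[, which.max(quad)]
    }
  }
  best_val
}

# features for n simulated series from one study case group
case_feats <- function(case, group, n, t_length, seed) {
  lapply(seq_len(n), function(i) {
    v <- simulate_series(case_params(case, group), t_length,
                         seed = seed + 17 * i)
    features_for_series(v, paste0("c", 1:4))
  })
}
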