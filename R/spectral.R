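# Spectral matrix estimation and envelope/scaling features.
#
# The spectral envelope of a categorical series at frequency w is the
# largest eigenvalue of the real part of the spectral matrix of its
# indicator encoding; the optimal scalings are the associated unit
# eigenvector. Estimation: periodogram of the indicator series, smoothed
# across frequencies with a symmetric kernel, then an eigendecomposition
# per Fourier frequency.

#' Periodogram matrices of a multivariate series
#'
#' Computes `I(s) = d(s) d(s)^H / T` where `d(s)` is the discrete Fourier
#' transform of the rows of `y`, for `s = 1, ..., T - 1` (the mean ordinate
#' `s = 0` is excluded from all downstream use). Each `I(s)` is a rank-one
#' Hermitian positive semi-definite matrix, and `I(T - s) = Conj(I(s))`.
#'
#' @param y Numeric T x p matrix (typically an indicator encoding from
#'   [encode_baseline()]).
#'
#' @return Complex array of dimension `c(p, p, T - 1)`; slice `s` is `I(s)`.
#' @export
periodogram_matrices <- function(y) {
  y <- as.matrix(y)
  t_length <- nrow(y)
  if (t_length < 2) abort("need at least T = 2 observations")
  p <- ncol(y)
  d <- stats::mvfft(y)[-1, , drop = FALSE] # rows s = 1 .. T-1
  pg <- array(0i, dim = c(p, p, t_length - 1))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      pg[i, j, ] <- d[, i] * Conj(d[, j]) / t_length
    }
  }
  pg
}

#' Smoothing kernel weights
#'
#' Symmetric nonnegative weights summing to one over a span of
#' `2 * bandwidth + 1` periodogram ordinates. The modified Daniell kernel
#' (`"mdaniell"`, the default elsewhere in the package) halves the two
#' endpoint weights; `"daniell"` is the plain moving average.
#'
#' @param bandwidth Integer half-width `B >= 0` of the smoothing window.
#' @param kernel `"mdaniell"` or `"daniell"`.
#' @return Numeric vector of length `2 * bandwidth + 1`.
#' @export
spectral_weights <- function(bandwidth, kernel = c("mdaniell", "daniell")) {
  kernel <- match.arg(kernel)
  b <- as.integer(bandwidth)
  if (b < 0) abort("`bandwidth` must be a nonnegative integer")
  if (b == 0) return(1)
  if (kernel == "daniell") rep(1 / (2 * b + 1), 2 * b + 1)
  else c(0.5, rep(1, 2 * b - 1), 0.5) / (2 * b)
}

resolve_bandwidth <- function(bandwidth, t_length) {
  if (is.character(bandwidth)) {
    if (!identical(bandwidth, "sqrt")) {
      abort("`bandwidth` must be \"sqrt\" or a nonnegative integer")
    }
    floor(sqrt(t_length))
  } else {
    b <- as.integer(bandwidth)
    if (is.na(b) || b < 0) abort("`bandwidth` must be \"sqrt\" or a nonnegative integer")
    b
  }
}

#' Smoothed periodogram estimate of the spectral matrix
#'
#' Averages `2 * bandwidth + 1` periodogram ordinates around each Fourier
#' frequency `w_s = s / t_length`, `s = 1, ..., K = floor((t_length - 1)/2)`,
#' with symmetric weights summing to one. Window indices falling below zero
#' are resolved by conjugate symmetry (`I(-u) = Conj(I(u))`); the excluded
#' mean ordinate `s = 0` is dropped from the window and the remaining
#' weights renormalized.
#'
#' @param pg Complex array `c(p, p, S)` of periodogram matrices for
#'   `s = 1, ..., S` (from [periodogram_matrices()], possibly interpolated),
#'   with `S = t_length - 1`.
#' @param t_length Series length T defining the Fourier grid.
#' @param bandwidth `"sqrt"` for `floor(sqrt(t_length))` (the default used
#'   throughout), or an explicit nonnegative integer. `bandwidth = 0` is the
#'   identity smoother (raw periodogram).
#' @param kernel Kernel name passed to [spectral_weights()].
#' @param weights Optional explicit weight vector of length
#'   `2 * bandwidth + 1` (overrides `kernel`); must be nonnegative,
#'   symmetric, and sum to one.
#'
#' @return An object of class `spec_matrix_estimate`: a list with `freqs`
#'   (length K), `f_hat` (complex array `c(p, p, K)`), `bandwidth`,
#'   `weights`, and `t_length`.
#' @export
smooth_periodogram <- function(pg, t_length, bandwidth = "sqrt",
                               kernel = c("mdaniell", "daniell"),
                               weights = NULL) {
  stopifnot(is.array(pg), length(dim(pg)) == 3)
  p <- dim(pg)[1]
  s_max <- dim(pg)[3]
  if (s_max != t_length - 1) {
    abort("`pg` must hold ordinates s = 1 .. t_length - 1")
  }
  b <- resolve_bandwidth(bandwidth, t_length)
  if (2 * b + 1 >= t_length - 1) {
    abort(paste0("smoothing span 2*", b, "+1 must be smaller than t_length - 1 = ",
                 t_length - 1))
  }
  if (is.null(weights)) {
    weights <- spectral_weights(b, match.arg(kernel))
  } else {
    if (length(weights) != 2 * b + 1) {
      abort("`weights` must have length 2 * bandwidth + 1")
    }
    if (any(weights < 0)) abort("`weights` must be nonnegative")
    if (max(abs(weights - rev(weights))) > 1e-12) abort("`weights` must be symmetric")
    if (abs(sum(weights) - 1) > 1e-10) abort("`weights` must sum to 1")
  }
  k <- (t_length - 1) %/% 2
  num <- array(0i, dim = c(p, p, k))
  wsum <- numeric(k)
  s <- seq_len(k)
  for (jj in seq_along(weights)) {
    j <- jj - b - 1L
    w <- weights[jj]
    u <- s + j
    pos <- which(u >= 1)
    neg <- which(u <= -1)
    if (length(pos)) {
      num[, , pos] <- num[, , pos, drop = FALSE] + w * pg[, , u[pos], drop = FALSE]
      wsum[pos] <- wsum[pos] + w
    }
    if (length(neg)) {
      num[, , neg] <- num[, , neg, drop = FALSE] + w * Conj(pg[, , -u[neg], drop = FALSE])
      wsum[neg] <- wsum[neg] + w
    }
    # u == 0 (the mean ordinate) is dropped; wsum renormalizes below
  }
  f_hat <- num / rep(wsum, each = p * p)
  structure(
    list(freqs = s / t_length, f_hat = f_hat, bandwidth = b,
         weights = weights, t_length = t_length),
    class = "spec_matrix_estimate")
}

#' Spectral envelope and optimal scalings from a spectral matrix estimate
#'
#' For each frequency, the envelope `lam[s]` is the largest eigenvalue of
#' the real part of the estimated spectral matrix, and `gam[, s]` a
#' corresponding unit eigenvector. Eigenvectors are sign-normalized so that
#' their first entry of magnitude above `1e-8` is positive; if the two
#' largest eigenvalues coincide to within `1e-10` relative (a violation of
#' the distinct-top-eigenvalue assumption the features rely on), the
#' solver's eigenvector is kept and a warning is emitted.
#'
#' @param sme A `spec_matrix_estimate` from [smooth_periodogram()].
#'
#' @return An object of class `envelope_scalings`: list with `freqs`,
#'   `lam` (length K), and `gam` (`(m - 1) x K`, unit columns).
#' @export
envelope_scalings <- function(sme) {
  stopifnot(inherits(sme, "spec_matrix_estimate"))
  f_hat <- sme$f_hat
  if (!all(is.finite(Re(f_hat))) || !all(is.finite(Im(f_hat)))) {
    abort("spectral matrix estimate contains non-finite entries")
  }
  p <- dim(f_hat)[1]
  k <- dim(f_hat)[3]
  lam <- numeric(k)
  gam <- matrix(0, p, k)
  n_degen <- 0L
  for (s in seq_len(k)) {
    m_re <- matrix(Re(f_hat[, , s]), p, p)
    m_re <- (m_re + t(m_re)) / 2
    e <- tryCatch(eigen(m_re, symmetric = TRUE),
                  error = function(cnd) {
                    abort(paste0("eigendecomposition failed at frequency index ", s,
                                 ": ", conditionMessage(cnd)))
                  })
    lam[s] <- e$values[1]
    if (p >= 2 && abs(e$values[1] - e$values[2]) <= 1e-10 * abs(e$values[1])) {
      n_degen <- n_degen + 1L
    }
    gam[, s] <- fix_sign(e$vectors[, 1])
  }
  if (n_degen > 0) {
    warn(paste0("top eigenvalue numerically non-distinct at ", n_degen,
                " of ", k, " frequencies; scalings there are not uniquely defined"))
  }
  structure(list(freqs = sme$freqs, lam = lam, gam = gam),
            class = "envelope_scalings")
}

# first entry with |.| > 1e-8 made positive; all-below-threshold: warn, keep
fix_sign <- function(v, tol = 1e-8) {
  i <- which(abs(v) > tol)
  if (length(i) == 0) {
    warn("eigenvector has no entry above the sign-convention threshold; sign left as-is")
    return(v)
  }
  if (v[i[1]] < 0) -v else v
}

#' Envelope/scaling features of a single categorical series
#'
#' Pipeline: baseline encoding, periodogram, kernel smoothing with
#' `bandwidth = floor(sqrt(T))` by default, and per-frequency
#' eigendecomposition. Returns `K = floor((T - 1)/2)` feature frequencies.
#'
#' @inheritParams encode_baseline
#' @inheritParams smooth_periodogram
#' @return An `envelope_scalings` object (see [envelope_scalings()]).
#' @export
features_for_series <- function(values, state_space, ref_state = NULL,
                                bandwidth = "sqrt",
                                kernel = c("mdaniell", "daniell")) {
  y <- encode_baseline(values, state_space, ref_state)
  if (nrow(y) < 4) abort("series too short: need T >= 4")
  sme <- smooth_periodogram(periodogram_matrices(y), nrow(y),
                            bandwidth = bandwidth, kernel = kernel)
  envelope_scalings(sme)
}

# --- variable-length support: periodogram interpolation ----------------------

# Linearly interpolate periodogram ordinates (real and imaginary parts
# elementwise) from the Fourier grid of `y`'s own length onto the grid
# s / t_target, s = 1 .. t_target - 1. Exact pass-through when lengths match.
pgram_on_grid <- function(y, t_target) {
  t_own <- nrow(y)
  pg <- periodogram_matrices(y)
  if (t_own == t_target) return(pg)
  if (t_own < t_target) {
    abort("can only interpolate onto the grid of a shorter (or equal) series")
  }
  p <- dim(pg)[1]
  own_freqs <- seq_len(t_own - 1) / t_own
  target_freqs <- seq_len(t_target - 1) / t_target
  out <- array(0i, dim = c(p, p, t_target - 1))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      re <- stats::approx(own_freqs, Re(pg[i, j, ]), xout = target_freqs)$y
      im <- stats::approx(own_freqs, Im(pg[i, j, ]), xout = target_freqs)$y
      out[i, j, ] <- complex(real = re, imaginary = im)
    }
  }
  out
}

#' Features for series of differing lengths on a common frequency grid
#'
#' Periodogram ordinates of every series are linearly interpolated
#' (elementwise, real and imaginary parts separately) onto the Fourier grid
#' of the shortest series; smoothing and eigendecomposition then proceed on
#' that grid, so all returned features share
#' `K = floor((T_min - 1)/2)` frequencies. With equal lengths this reduces
#' exactly to [features_for_series()] per series.
#'
#' @param series_list List (length >= 2) of character vectors of states.
#' @inheritParams features_for_series
#' @return List of `envelope_scalings` objects sharing a common `freqs`.
#' @export
interpolate_features <- function(series_list, state_space, ref_state = NULL,
                                 bandwidth = "sqrt",
                                 kernel = c("mdaniell", "daniell")) {
  if (length(series_list) < 2) abort("need at least 2 series")
  kernel <- match.arg(kernel)
  t_min <- min(vapply(series_list, length, integer(1)))
  if (t_min < 4) abort("shortest series too short: need T >= 4")
  lapply(series_list, function(v) {
    y <- encode_baseline(v, state_space, ref_state)
    sme <- smooth_periodogram(pgram_on_grid(y, t_min), t_min,
                              bandwidth = bandwidth, kernel = kernel)
    envelope_scalings(sme)
  })
}

# --- tidy wrapper -------------------------------------------------------------

#' Per-series envelope and scaling features as a tibble
#'
#' Computes envelope/scaling features for every series in a long-format
#' table. Series of differing lengths are placed on the Fourier grid of the
#' shortest series by periodogram interpolation, so all series share the
#' same frequencies.
#'
#' @param data Data frame with columns `series_id`, `time_index`, `state`.
#' @inheritParams prepare_series
#' @inheritParams smooth_periodogram
#' @return A tibble (class `envsca_features`) with columns `series_id`,
#'   `freq`, `lambda`, and `gamma_1 ... gamma_{m-1}` (one per non-reference
#'   category, in state-space order; the mapping is in
#'   `attr(., "categories")`).
#' @examples
#' sim <- simulate_case(1, n_per_group = 2, t_length = 64, seed = 1)
#' env_features(sim, state_space = attr(sim, "state_space"))
#' @export
env_features <- function(data, state_space = NULL, ref_state = NULL,
                         bandwidth = "sqrt",
                         kernel = c("mdaniell", "daniell")) {
  kernel <- match.arg(kernel)
  prep <- prepare_series(data, state_space, ref_state)
  lens <- vapply(prep$series, length, integer(1))
  feats <-
    if (length(prep$series) > 1 && length(unique(lens)) > 1) {
      interpolate_features(prep$series, prep$state_space, prep$ref_state,
                           bandwidth, kernel)
    } else {
      lapply(prep$series, features_for_series, state_space = prep$state_space,
             ref_state = prep$ref_state, bandwidth = bandwidth, kernel = kernel)
    }
  categories <- setdiff(prep$state_space, prep$ref_state)
  rows <- purrr::imap(feats, function(f, id) {
    g <- t(f$gam)
    colnames(g) <- paste0("gamma_", seq_along(categories))
    dplyr::bind_cols(
      tibble::tibble(series_id = id, freq = f$freqs, lambda = f$lam),
      tibble::as_tibble(g))
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("envsca_features", class(out)),
            state_space = prep$state_space,
            ref_state = prep$ref_state,
            categories = categories)
}

#' @describeIn env_features Plot per-series spectral envelopes.
#' @param object An `envsca_features` tibble.
#' @param ... Unused.
#' @method autoplot envsca_features
#' @export
autoplot.envsca_features <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$freq, y = .data$lambda,
                               group = .data$series_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "frequency (cycles per observation)",
                  y = "spectral envelope") +
    ggplot2::theme_minimal()
}
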