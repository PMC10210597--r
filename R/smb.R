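# Spectral-matrix-based (SMB) baseline classifiers.
#
# Instead of eigen-features, these compare a test series' whole smoothed
# spectral matrix against per-group mean matrices, averaging a disparity
# over frequencies:
#   TVD: 1 - <A, B>_F / (||A||_F ||B||_F)
#   KL:  tr(A B^-1) - log det(A B^-1) - p        (quasi-likelihood form)
#   CH:  log det(tA + (1-t)B) - t log det A - (1-t) log det B,  t in (0, 1)
# KL and CH require nonsingular matrices; a ridge of 1e-8 * trace / p is
# added to stabilize near-singular estimates.

herm_eigvals <- function(a) {
  eigen((a + Conj(t(a))) / 2, symmetric = TRUE, only.values = TRUE)$values
}

ridge_reg <- function(a) {
  p <- nrow(a)
  eps <- 1e-8 * Re(sum(diag(a))) / p
  a + diag(eps, p)
}

logdet_h <- function(a) {
  v <- herm_eigvals(a)
  if (any(v <= 0)) {
    abort("singular (or indefinite) spectral matrix; cannot take log-determinant")
  }
  sum(log(v))
}

#' Fit a spectral-matrix-based group model
#'
#' Averages the smoothed spectral matrix estimates of the training series
#' elementwise within each group (averaging preserves the Hermitian
#' property exactly and positive semi-definiteness by convexity).
#'
#' @param smes List of `spec_matrix_estimate` objects on a common grid.
#' @param labels Group label per estimate.
#' @param kind Disparity: `"TVD"`, `"KL"`, or `"CH"`.
#' @return List of class `smb_model` with `group_labels`, `n_per_group`,
#'   `f_bar` (complex array `(p, p, K, J)`), `freqs`, `kind`, and `theta`
#'   (Chernoff parameter; `NULL` until tuned or supplied).
#' @export
smb_fit <- function(smes, labels, kind = c("TVD", "KL", "CH")) {
  kind <- match.arg(kind)
  if (length(smes) != length(labels)) abort("one label per estimate required")
  ks <- unname(vapply(smes, function(s) dim(s$f_hat)[3], integer(1)))
  if (length(unique(ks)) != 1) abort("estimates must share a common frequency grid")
  fl <- factor(labels)
  if (any(table(fl) < 1)) abort("every group needs at least one series")
  p <- dim(smes[[1]]$f_hat)[1]
  k <- ks[1]
  glabs <- levels(fl)
  f_bar <- array(0i, dim = c(p, p, k, length(glabs)))
  n_j <- tabulate(as.integer(fl), nbins = length(glabs))
  for (i in seq_along(smes)) {
    j <- as.integer(fl)[i]
    f_bar[, , , j] <- f_bar[, , , j] + smes[[i]]$f_hat
  }
  for (j in seq_along(glabs)) f_bar[, , , j] <- f_bar[, , , j] / n_j[j]
  structure(list(group_labels = glabs, n_per_group = n_j, f_bar = f_bar,
                 freqs = smes[[1]]$freqs, kind = kind, theta = NULL),
            class = "smb_model")
}

# disparity between two spectral matrix arrays (p, p, K), averaged over K
smb_disparity <- function(fa, fb, kind, theta = 0.5) {
  k <- dim(fa)[3]
  p <- dim(fa)[1]
  total <- 0
  for (s in seq_len(k)) {
    a <- matrix(fa[, , s], p, p)
    b <- matrix(fb[, , s], p, p)
    total <- total + switch(
      kind,
      TVD = {
        na <- sqrt(Re(sum(a * Conj(a))))
        nb <- sqrt(Re(sum(b * Conj(b))))
        if (na == 0 && nb == 0) 0
        else if (na == 0 || nb == 0) 1
        else 1 - Re(sum(a * Conj(b))) / (na * nb)
      },
      KL = {
        a <- ridge_reg(a); b <- ridge_reg(b)
        ratio <- tryCatch(solve(b, a), error = function(cnd) {
          abort(paste0("singular group spectral matrix at frequency index ", s))
        })
        Re(sum(diag(ratio))) - (logdet_h(a) - logdet_h(b)) - p
      },
      CH = {
        a <- ridge_reg(a); b <- ridge_reg(b)
        logdet_h(theta * a + (1 - theta) * b) -
          theta * logdet_h(a) - (1 - theta) * logdet_h(b)
      })
  }
  total / k
}

#' Disparity between a test spectral estimate and a group mean
#'
#' @param sme A `spec_matrix_estimate` for the test series.
#' @param model An `smb_model` from [smb_fit()].
#' @param j Group index (1-based).
#' @param kind Optionally override the model's disparity kind.
#' @param theta Chernoff parameter in `(0, 1)` (only for `kind = "CH"`;
#'   defaults to the model's tuned value, else 0.5).
#' @return Nonnegative scalar (frequency-averaged disparity).
#' @export
smb_distance <- function(sme, model, j, kind = NULL, theta = NULL) {
  stopifnot(inherits(model, "smb_model"))
  kind <- kind %||% model$kind
  theta <- theta %||% model$theta %||% 0.5
  if (kind == "CH" && (theta <= 0 || theta >= 1)) {
    abort("Chernoff `theta` must be in (0, 1)")
  }
  if (!j %in% seq_along(model$group_labels)) abort("invalid group index `j`")
  fa <- sme$f_hat
  if (!all(dim(fa) == dim(model$f_bar)[1:3])) {
    abort(paste0("shape mismatch: test estimate is ",
                 paste(dim(fa), collapse = "x"), ", model expects ",
                 paste(dim(model$f_bar)[1:3], collapse = "x")))
  }
  fb <- array(model$f_bar[, , , j], dim = dim(model$f_bar)[1:3])
  smb_disparity(fa, fb, kind, theta)
}

# LOO tuning of the Chernoff parameter: hold each training series out,
# recompute its own group mean without it, classify by CH distance; keep
# the first theta attaining the best LOO rate (deterministic).
tune_theta <- function(smes, labels, theta_grid = seq(0.1, 0.9, by = 0.1)) {
  fl <- factor(labels)
  j_of <- as.integer(fl)
  n_j <- tabulate(j_of, nbins = nlevels(fl))
  if (any(n_j < 2)) abort("Chernoff LOO tuning needs at least 2 series per group")
  p <- dim(smes[[1]]$f_hat)[1]
  k <- dim(smes[[1]]$f_hat)[3]
  n_groups <- nlevels(fl)
  sums <- array(0i, dim = c(p, p, k, n_groups))
  for (i in seq_along(smes)) {
    sums[, , , j_of[i]] <- sums[, , , j_of[i]] + smes[[i]]$f_hat
  }
  rates <- vapply(theta_grid, function(theta) {
    correct <- 0L
    for (r in seq_along(smes)) {
      d <- vapply(seq_len(n_groups), function(j) {
        own <- j_of[r] == j
        fbar <- (array(sums[, , , j], dim = c(p, p, k)) -
                   if (own) smes[[r]]$f_hat else 0) / (n_j[j] - own)
        smb_disparity(smes[[r]]$f_hat, fbar, "CH", theta)
      }, numeric(1))
      correct <- correct + (which.min(d) == j_of[r])
    }
    correct / length(smes)
  }, numeric(1))
  theta_grid[which.max(rates)]
}
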