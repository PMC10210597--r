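# Distance-based classifiers on envelope/scaling features.
#
# Group features are elementwise averages of per-series features. Distances:
#   env:    || lam_r - Lambda_j ||_2^2                    (envelope only)
#   sca:    || gam_r - Gamma_j ||_F^2                     (scalings only)
#   envsca: kappa * env / ||lam_r||_2^2
#           + (1 - kappa) * sca / ||gam_r||_F^2           (adaptive mix)
# The mixing weight kappa is tuned by leave-one-out cross-validation on an
# 11-point grid, with group means honestly recomputed without the held-out
# series.

# list of envelope_scalings -> lam (K x N), gam (p, K, N)
feats_to_mats <- function(features) {
  ks <- unname(vapply(features, function(f) length(f$lam), integer(1)))
  if (length(unique(ks)) != 1) {
    abort("features have differing numbers of frequencies; put them on a common grid with interpolate_features()")
  }
  lam <- vapply(features, function(f) f$lam, numeric(ks[1]))
  lam <- matrix(lam, nrow = ks[1]) # guard K = 1 simplification
  p <- nrow(features[[1]]$gam)
  gam <- vapply(features, function(f) f$gam, matrix(0, p, ks[1]))
  gam <- array(gam, dim = c(p, ks[1], length(features)))
  list(lam = lam, gam = gam)
}

# gamma row indices (in the p*K flattened layout) for a frequency subset
sel_rows <- function(select, p) {
  as.vector(outer(seq_len(p), (select - 1L) * p, `+`))
}

#' Group-mean envelope and scaling features
#'
#' Averages the per-series spectral envelopes and optimal scalings within
#' each group (plain arithmetic means; averaged scaling columns are not
#' renormalized, so their norm shrinks when series disagree).
#'
#' @param features List of `envelope_scalings` objects on a common
#'   frequency grid (use [interpolate_features()] if lengths differ).
#' @param labels Vector of group labels, one per feature.
#'
#' @return A list of class `envsca_group_features` with `group_labels`,
#'   `n_per_group`, `Lambda` (J x K matrix, one row per group), `Gamma`
#'   (array `(m - 1) x K x J`), and `freqs`.
#' @export
group_features <- function(features, labels) {
  if (length(features) != length(labels)) {
    abort("`labels` must have one entry per feature")
  }
  mats <- feats_to_mats(features)
  fl <- factor(labels)
  if (any(table(fl) < 1)) abort("every group needs at least one series")
  glabs <- levels(fl)
  j_of <- as.integer(fl)
  n_j <- tabulate(j_of, nbins = length(glabs))
  k <- nrow(mats$lam)
  p <- dim(mats$gam)[1]
  lam_bar <- t(rowsum(t(mats$lam), fl) / n_j)     # K x J
  dimnames(lam_bar) <- NULL
  gam_bar <- array(0, dim = c(p, k, length(glabs)))
  for (j in seq_along(glabs)) {
    gam_bar[, , j] <- rowMeans(mats$gam[, , j_of == j, drop = FALSE], dims = 2)
  }
  structure(
    list(group_labels = glabs, n_per_group = n_j,
         Lambda = t(lam_bar), Gamma = gam_bar,
         freqs = features[[1]]$freqs),
    class = "envsca_group_features")
}

#' Squared distances between a test feature and a group feature
#'
#' `dist_env()` is the squared L2 distance between envelopes, `dist_sca()`
#' the squared Frobenius distance between scaling matrices, and
#' `dist_envsca()` their convex combination after normalizing each term by
#' the test series' own feature norm (computed over the same frequency
#' subsets). With the full frequency set the scaling normalizer equals K
#' exactly, since scaling columns are unit vectors.
#'
#' @param lam,group_lam Envelope vectors (length K) of the test series and
#'   the group mean.
#' @param select Optional subset of frequency indices to restrict to.
#' @return Nonnegative scalar.
#' @export
dist_env <- function(lam, group_lam, select = NULL) {
  if (length(lam) != length(group_lam)) {
    abort("envelope lengths differ; features must share the frequency grid")
  }
  if (!is.null(select)) {
    lam <- lam[select]
    group_lam <- group_lam[select]
  }
  sum((lam - group_lam)^2)
}

#' @rdname dist_env
#' @param gam,group_gam Scaling matrices (`(m - 1) x K`) of the test series
#'   and the group mean.
#' @export
dist_sca <- function(gam, group_gam, select = NULL) {
  if (!all(dim(gam) == dim(group_gam))) {
    abort("scaling matrix shapes differ; features must share the frequency grid")
  }
  if (!is.null(select)) {
    gam <- gam[, select, drop = FALSE]
    group_gam <- group_gam[, select, drop = FALSE]
  }
  sum((gam - group_gam)^2)
}

#' @rdname dist_env
#' @param kappa Mixing weight in `[0, 1]`; 1 uses only envelope
#'   differences, 0 only scaling differences.
#' @param select_env,select_sca Frequency subsets for the envelope and
#'   scaling terms (and their normalizers).
#' @export
dist_envsca <- function(lam, gam, group_lam, group_gam, kappa,
                        select_env = NULL, select_sca = NULL) {
  if (kappa < 0 || kappa > 1) abort("`kappa` must be in [0, 1]")
  env_norm <- if (is.null(select_env)) sum(lam^2) else sum(lam[select_env]^2)
  sca_norm <- if (is.null(select_sca)) sum(gam^2) else sum(gam[, select_sca]^2)
  if (env_norm <= 0 || sca_norm <= 0) {
    abort("degenerate test series: feature norm over the selected frequencies is zero")
  }
  kappa * dist_env(lam, group_lam, select_env) / env_norm +
    (1 - kappa) * dist_sca(gam, group_gam, select_sca) / sca_norm
}

#' Select the most discriminative frequencies
#'
#' Ranks frequencies by the between-group sum of squared differences of the
#' group-mean envelopes (`delta_env`) and scalings (`delta_sca`) over all
#' unordered group pairs, and keeps the top `ceiling(prop * K)` of each
#' (independently for the two feature types; ties broken toward the lower
#' frequency index).
#'
#' @param gf An `envsca_group_features` object (>= 2 groups).
#' @param prop Proportion of frequencies to keep, in `(0, 1]`.
#' @return List with sorted integer index vectors `env` and `sca`.
#' @export
select_frequencies <- function(gf, prop = 1) {
  stopifnot(inherits(gf, "envsca_group_features"))
  if (prop <= 0 || prop > 1) abort("`prop` must be in (0, 1]")
  n_groups <- length(gf$group_labels)
  if (n_groups < 2) abort("frequency selection needs at least 2 groups")
  k <- ncol(gf$Lambda)
  delta_env <- numeric(k)
  delta_sca <- numeric(k)
  for (j in seq_len(n_groups - 1)) {
    for (h in seq(j + 1, n_groups)) {
      delta_env <- delta_env + (gf$Lambda[j, ] - gf$Lambda[h, ])^2
      delta_sca <- delta_sca + colSums((gf$Gamma[, , j] - gf$Gamma[, , h])^2)
    }
  }
  n_keep <- ceiling(prop * k)
  list(env = sort(order(-delta_env)[seq_len(n_keep)]),
       sca = sort(order(-delta_sca)[seq_len(n_keep)]))
}

# normalized env/sca distance matrices (N x J) of features against group
# means; when loo = TRUE the own-group mean is recomputed without the series
norm_dist_mats <- function(lam, gam, j_of, n_j, selE, selS, loo = FALSE) {
  k <- nrow(lam)
  p <- dim(gam)[1]
  n <- ncol(lam)
  n_groups <- length(n_j)
  g_flat <- matrix(gam, nrow = p * k)
  ind <- matrix(0, n, n_groups)
  ind[cbind(seq_len(n), j_of)] <- 1
  slam <- lam %*% ind                       # K x J group sums
  sgam <- g_flat %*% ind                    # pK x J group sums
  rowsE <- selE
  rowsS <- sel_rows(selS, p)
  a <- matrix(0, n, n_groups)
  b <- matrix(0, n, n_groups)
  for (r in seq_len(n)) {
    lam_r <- lam[rowsE, r]
    gam_r <- g_flat[rowsS, r]
    env_norm <- sum(lam_r^2)
    sca_norm <- sum(gam_r^2)
    if (env_norm <= 0 || sca_norm <= 0) {
      abort(paste0("degenerate series ", r,
                   ": feature norm over selected frequencies is zero"))
    }
    for (j in seq_len(n_groups)) {
      drop_own <- loo && j_of[r] == j
      denom <- n_j[j] - drop_own
      lam_j <- (slam[rowsE, j] - if (drop_own) lam_r else 0) / denom
      gam_j <- (sgam[rowsS, j] - if (drop_own) gam_r else 0) / denom
      a[r, j] <- sum((lam_r - lam_j)^2) / env_norm
      b[r, j] <- sum((gam_r - gam_j)^2) / sca_norm
    }
  }
  list(env = a, sca = b)
}

#' Tune the envelope/scaling mixing weight by leave-one-out cross-validation
#'
#' For each candidate kappa, every training series is held out in turn, the
#' group features are recomputed without it, and the held-out series is
#' classified by the adaptive distance; the kappa maximizing the LOO
#' correct-classification rate is returned, with ties broken toward the
#' largest kappa. The procedure is deterministic given the training set.
#'
#' @inheritParams group_features
#' @param kappa_grid Candidate kappa values (default `0, 0.1, ..., 1`).
#' @param select_env,select_sca Optional frequency subsets (defaults: all).
#' @return List with `kappa`, `loo_rate` (rate achieved at `kappa`), and
#'   `grid_rates` (named vector of LOO rates per candidate).
#' @export
tune_kappa <- function(features, labels, kappa_grid = seq(0, 1, by = 0.1),
                       select_env = NULL, select_sca = NULL) {
  mats <- feats_to_mats(features)
  fl <- factor(labels)
  tune_core(mats$lam, mats$gam, as.integer(fl),
            tabulate(as.integer(fl), nlevels(fl)), kappa_grid,
            select_env %||% seq_len(nrow(mats$lam)),
            select_sca %||% seq_len(nrow(mats$lam)))
}

tune_core <- function(lam, gam, j_of, n_j, kappa_grid, selE, selS) {
  if (length(kappa_grid) < 1) abort("`kappa_grid` must be nonempty")
  if (any(kappa_grid < 0 | kappa_grid > 1)) abort("kappa values must be in [0, 1]")
  if (any(n_j < 2)) {
    abort("leave-one-out tuning needs at least 2 series per group")
  }
  d <- norm_dist_mats(lam, gam, j_of, n_j, selE, selS, loo = TRUE)
  rates <- vapply(kappa_grid, function(kap) {
    score <- kap * d$env + (1 - kap) * d$sca
    mean(max.col(-score, ties.method = "first") == j_of)
  }, numeric(1))
  best <- max(which(rates == max(rates))) # ties toward the largest kappa
  list(kappa = kappa_grid[best], loo_rate = rates[best],
       grid_rates = stats::setNames(rates, format(kappa_grid)))
}

# --- model fitting ------------------------------------------------------------

new_envsca_fit <- function(fields) {
  structure(c(fields, list(version = "1.0")), class = "envsca_fit")
}

#' Fit a categorical time series classifier
#'
#' Computes envelope/scaling features for every training series (on the
#' Fourier grid of the shortest series when lengths differ) and builds a
#' distance-based classifier. Methods `"env"`, `"sca"`, and `"envsca"`
#' (adaptive, default) use the eigen-features; methods `"smb_tvd"`,
#' `"smb_kl"`, and `"smb_ch"` are spectral-matrix-based baselines that
#' compare whole smoothed spectral matrices by total variation,
#' Kullback-Leibler, or Chernoff disparity.
#'
#' @param data Long data frame with columns `series_id`, `time_index`,
#'   `state`, and (if `labels` is `NULL`) `group`.
#' @param labels Optional data frame with columns `series_id`, `group`.
#' @param method Classifier type (see Details above).
#' @param state_space,ref_state State space and reference category (see
#'   [prepare_series()]); inferred / last state by default.
#' @param bandwidth,kernel Spectral smoothing controls (see
#'   [smooth_periodogram()]).
#' @param kappa `"auto"` (LOO-tuned, default) or a fixed value in `[0, 1]`;
#'   only used by `method = "envsca"`.
#' @param kappa_grid Grid searched when `kappa = "auto"`.
#' @param select_prop Proportion of most-discriminative frequencies kept
#'   for the distances (default 1: all frequencies).
#' @param theta_grid Chernoff parameter grid searched by LOO for
#'   `method = "smb_ch"`.
#'
#' @return An object of class `envsca_fit`; see [predict.envsca_fit()],
#'   [tidy.envsca_fit()], [glance.envsca_fit()], [autoplot.envsca_fit()].
#' @examples
#' train <- simulate_case(1, n_per_group = 5, t_length = 100, seed = 1)
#' fit <- envsca_fit(train, state_space = attr(train, "state_space"))
#' glance(fit)
#' @export
envsca_fit <- function(data, labels = NULL,
                       method = c("envsca", "env", "sca",
                                  "smb_tvd", "smb_kl", "smb_ch"),
                       state_space = NULL, ref_state = NULL,
                       bandwidth = "sqrt", kernel = c("mdaniell", "daniell"),
                       kappa = "auto", kappa_grid = seq(0, 1, by = 0.1),
                       select_prop = 1, theta_grid = seq(0.1, 0.9, by = 0.1)) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  state_space <- state_space %||% attr(data, "state_space")
  ref_state <- ref_state %||% attr(data, "ref_state")
  prep <- prepare_series(data, state_space, ref_state)
  if (is.null(labels)) {
    if (!"group" %in% names(data)) {
      abort("supply `labels` or include a `group` column in `data`")
    }
    labels <- dplyr::distinct(dplyr::as_tibble(data),
                              .data$series_id, .data$group)
  }
  lab <- labels$group[match(names(prep$series), labels$series_id)]
  if (anyNA(lab)) abort("`labels` is missing labels for some series")

  t_ref <- min(vapply(prep$series, length, integer(1)))
  b <- resolve_bandwidth(bandwidth, t_ref)
  weights <- spectral_weights(b, kernel)
  smes <- lapply(prep$series, function(v) {
    y <- encode_baseline(v, prep$state_space, prep$ref_state)
    smooth_periodogram(pgram_on_grid(y, t_ref), t_ref, bandwidth = b,
                       weights = weights)
  })
  feats <- lapply(smes, envelope_scalings)
  fit_core(
    feats = feats, smes = if (startsWith(method, "smb")) smes else NULL,
    labels = lab, method = method, kappa = kappa, kappa_grid = kappa_grid,
    select_prop = select_prop, theta_grid = theta_grid,
    meta = list(state_space = prep$state_space, ref_state = prep$ref_state,
                categories = setdiff(prep$state_space, prep$ref_state),
                t_ref = t_ref, bandwidth = b, kernel = kernel,
                weights = weights))
}

fit_core <- function(feats, smes, labels, method, kappa, kappa_grid,
                     select_prop, theta_grid, meta) {
  gf <- group_features(feats, labels)
  mats <- feats_to_mats(feats)
  fl <- factor(labels, levels = gf$group_labels)
  k <- ncol(gf$Lambda)
  sel <- if (select_prop < 1) {
    select_frequencies(gf, select_prop)
  } else {
    list(env = seq_len(k), sca = seq_len(k))
  }
  kappa_hat <- NA_real_
  loo_rate <- NA_real_
  if (method == "envsca") {
    if (identical(kappa, "auto")) {
      tuned <- tune_core(mats$lam, mats$gam, as.integer(fl), gf$n_per_group,
                         kappa_grid, sel$env, sel$sca)
      kappa_hat <- tuned$kappa
      loo_rate <- tuned$loo_rate
    } else {
      kappa_hat <- as.numeric(kappa)
      if (is.na(kappa_hat) || kappa_hat < 0 || kappa_hat > 1) {
        abort("`kappa` must be \"auto\" or a number in [0, 1]")
      }
    }
  }
  smb <- NULL
  if (startsWith(method, "smb")) {
    kind <- toupper(sub("smb_", "", method))
    smb <- smb_fit(smes, labels, kind = kind)
    if (kind == "CH") {
      smb$theta <- tune_theta(smes, labels, theta_grid)
    }
  }
  new_envsca_fit(c(meta, list(
    method = method, group_labels = gf$group_labels,
    n_per_group = gf$n_per_group, freqs = gf$freqs, k = k,
    Lambda = gf$Lambda, Gamma = gf$Gamma,
    kappa = kappa_hat, loo_rate = loo_rate,
    select_prop = select_prop, selected_env = sel$env, selected_sca = sel$sca,
    smb = smb)))
}

# --- prediction ---------------------------------------------------------------

# distances of feature matrices to all groups under the model's method
distance_matrix <- function(model, mats, smes = NULL) {
  n_groups <- length(model$group_labels)
  method <- model$method
  if (startsWith(method, "smb")) {
    n <- length(smes)
    d <- matrix(0, n, n_groups)
    for (r in seq_len(n)) {
      for (j in seq_len(n_groups)) {
        d[r, j] <- smb_distance(smes[[r]], model$smb, j,
                                theta = model$smb$theta)
      }
    }
    return(d)
  }
  n <- ncol(mats$lam)
  d <- matrix(0, n, n_groups)
  for (r in seq_len(n)) {
    for (j in seq_len(n_groups)) {
      d[r, j] <- switch(
        method,
        env = dist_env(mats$lam[, r], model$Lambda[j, ], model$selected_env),
        sca = dist_sca(mats$gam[, , r], model$Gamma[, , j], model$selected_sca),
        envsca = dist_envsca(mats$lam[, r], mats$gam[, , r],
                             model$Lambda[j, ], model$Gamma[, , j],
                             model$kappa, model$selected_env,
                             model$selected_sca))
    }
  }
  d
}

predict_from_distances <- function(d, group_labels, series_ids) {
  pred <- max.col(-d, ties.method = "first") # tie -> lowest group index
  ties <- apply(d, 1, function(x) sum(x == min(x)) > 1)
  if (any(ties)) {
    inform(paste0("distance tie for series ",
                  paste(series_ids[ties], collapse = ", "),
                  "; assigned to the lowest-index group"))
  }
  out <- tibble::tibble(series_id = series_ids,
                        .pred_group = group_labels[pred])
  dmat <- tibble::as_tibble(as.data.frame(d))
  names(dmat) <- paste0("dist_", group_labels)
  dplyr::bind_cols(out, dmat)
}

#' Predict group membership for new categorical time series
#'
#' Test series are placed on the model's frequency grid (their periodogram
#' ordinates are interpolated when their length differs from the training
#' reference length) and assigned to the group at minimum distance.
#' Exact distance ties go to the lowest-index group and are reported.
#'
#' @param object A fitted `envsca_fit`.
#' @param newdata Long data frame with columns `series_id`, `time_index`,
#'   `state`.
#' @param ... Unused.
#' @return A tibble with `series_id`, `.pred_group`, and one distance
#'   column per group.
#' @export
predict.envsca_fit <- function(object, newdata, ...) {
  prep <- prepare_series(newdata, object$state_space, object$ref_state)
  short <- vapply(prep$series, length, integer(1)) < object$t_ref
  if (any(short)) {
    abort(paste0("series shorter than the model grid (T = ", object$t_ref,
                 "): ", paste(names(prep$series)[short], collapse = ", ")))
  }
  smes <- lapply(prep$series, function(v) {
    y <- encode_baseline(v, object$state_space, object$ref_state)
    if (ncol(y) != length(object$categories)) {
      abort(paste0("state-space mismatch: model has ", length(object$categories) + 1,
                   " states, data has ", ncol(y) + 1))
    }
    smooth_periodogram(pgram_on_grid(y, object$t_ref), object$t_ref,
                       bandwidth = object$bandwidth, weights = object$weights)
  })
  mats <- NULL
  if (!startsWith(object$method, "smb")) {
    mats <- feats_to_mats(lapply(smes, envelope_scalings))
  }
  d <- distance_matrix(object, mats, smes)
  predict_from_distances(d, object$group_labels, names(prep$series))
}
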