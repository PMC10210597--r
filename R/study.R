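# Monte-Carlo study driver.
#
# Per replication: simulate labeled training and test sets from the lag-1
# multinomial-logit presets, extract features once, fit every requested
# classifier on the training set (the adaptive one with LOO-tuned kappa),
# and score the test correct-classification rate. Seeding is derived per
# (replication, group, series, role), so results do not depend on the
# order in which series are generated.

# deterministic 31-bit seed mixing (all intermediates stay below 2^53)
mix_seed <- function(...) {
  h <- 0
  for (v in c(...)) h <- (h * 48271 + as.numeric(v) + 1) %% 2147483629
  as.integer(h + 1)
}

# indicator-encode an integer-coded series (reference = state m) and
# compute its spectral estimate and eigen-features
spec_and_feat <- function(x, m, t_length, b, weights, want_sme = FALSE) {
  y <- matrix(0, t_length, m - 1L)
  nonref <- which(x < m)
  y[cbind(nonref, x[nonref])] <- 1
  sme <- smooth_periodogram(periodogram_matrices(y), t_length,
                            bandwidth = b, weights = weights)
  list(feat = envelope_scalings(sme), sme = if (want_sme) sme else NULL)
}

# vectorized score matrices (series x groups); smaller score = closer
score_env <- function(lam, Lambda, selE) {
  lt <- lam[selE, , drop = FALSE]            # |sel| x R
  ls <- Lambda[, selE, drop = FALSE]         # J x |sel|
  sweep(-2 * t(lt) %*% t(ls), 2, rowSums(ls^2), "+")
}

score_sca <- function(gflat, Gflat, rowsS) {
  gt <- gflat[rowsS, , drop = FALSE]
  gs <- Gflat[rowsS, , drop = FALSE]         # pK x J
  sweep(-2 * t(gt) %*% gs, 2, colSums(gs^2), "+")
}

# normalized env/sca score matrices for the adaptive distance
norm_scores <- function(lam, gflat, Lambda, Gflat, selE, rowsS) {
  lt <- lam[selE, , drop = FALSE]
  ls <- Lambda[, selE, drop = FALSE]
  env_norm <- colSums(lt^2)
  a <- sweep(sweep(-2 * t(lt) %*% t(ls), 2, rowSums(ls^2), "+"), 1,
             env_norm, "+") / env_norm
  gt <- gflat[rowsS, , drop = FALSE]
  gs <- Gflat[rowsS, , drop = FALSE]
  sca_norm <- colSums(gt^2)
  b <- sweep(sweep(-2 * t(gt) %*% gs, 2, colSums(gs^2), "+"), 1,
             sca_norm, "+") / sca_norm
  list(env = a, sca = b)
}

#' Run a Monte-Carlo classification study
#'
#' Repeatedly simulates training and test collections from a study preset
#' (or the varying-m extension when `m` is supplied), fits the requested
#' classifiers, and reports the mean and standard deviation of test
#' correct-classification rates (percent) across replications, plus the
#' mean LOO-tuned kappa for the adaptive classifier. Fully deterministic
#' given `seed`.
#'
#' @inheritParams case_params
#' @param n_per_group Training series per group.
#' @param t_length Series length.
#' @param methods Subset of `c("envsca", "env", "sca", "smb_tvd",
#'   "smb_kl", "smb_ch")`.
#' @param reps Number of replications.
#' @param test_per_group Test series per group per replication.
#' @param seed Integer base seed.
#' @param m If non-`NULL`, use the varying-m extension of the Case 1 design
#'   with this many categories (two groups) instead of `case`.
#' @param bandwidth,kernel Spectral smoothing controls.
#' @param kappa_grid Grid for LOO tuning of the adaptive classifier.
#' @param burn_in Simulator burn-in.
#'
#' @return Tibble with columns `case`, `m`, `n_per_group`, `t_length`,
#'   `method`, `mean`, `sd`, `mean_kappa`, `reps`. Per-replication rates
#'   (a `reps x methods` matrix, in percent) and tuned kappas are attached
#'   as attributes `rates` and `kappas`.
#' @examples
#' run_study(1, n_per_group = 4, t_length = 64, reps = 2,
#'           test_per_group = 5, seed = 1)
#' @export
run_study <- function(case = 1, n_per_group = 20, t_length = 100,
                      methods = c("envsca", "env", "sca"),
                      reps = 100, test_per_group = 50, seed = 1,
                      m = NULL, bandwidth = "sqrt",
                      kernel = c("mdaniell", "daniell"),
                      kappa_grid = seq(0, 1, by = 0.1), burn_in = 100) {
  kernel <- match.arg(kernel)
  all_methods <- c("envsca", "env", "sca", "smb_tvd", "smb_kl", "smb_ch")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  if (reps < 1) abort("`reps` must be >= 1")
  if (n_per_group < 2) abort("need `n_per_group` >= 2 (LOO tuning feasibility)")
  if (test_per_group < 1) abort("`test_per_group` must be >= 1")
  params <- if (is.null(m)) {
    lapply(seq_len(case_n_groups(case)), function(j) case_params(case, j))
  } else {
    list(varying_m_params(m, 1), varying_m_params(m, 2))
  }
  m_states <- nrow(params[[1]]) + 1L
  n_groups <- length(params)
  cums <- lapply(params, function(a) {
    t(apply(mlogit_transition_matrix(a), 1, cumsum))
  })
  b <- resolve_bandwidth(bandwidth, t_length)
  weights <- spectral_weights(b, kernel)
  k <- (t_length - 1) %/% 2
  p <- m_states - 1L
  selE <- seq_len(k)
  rowsS <- seq_len(p * k)
  want_sme <- any(startsWith(methods, "smb"))
  train_lab <- rep(seq_len(n_groups), each = n_per_group)
  test_lab <- rep(seq_len(n_groups), each = test_per_group)
  n_j <- rep(n_per_group, n_groups)

  sim_block <- function(rep, j, n, role) {
    lapply(seq_len(n), function(i) {
      sim_chain(cums[[j]], m_states, t_length, burn_in,
                mix_seed(seed, rep, j, i, role))
    })
  }
  feats_block <- function(xs) {
    lapply(xs, spec_and_feat, m = m_states, t_length = t_length, b = b,
           weights = weights, want_sme = want_sme)
  }
  to_mats <- function(fs) {
    lam <- vapply(fs, function(f) f$feat$lam, numeric(k))
    gflat <- vapply(fs, function(f) as.vector(f$feat$gam), numeric(p * k))
    list(lam = unname(matrix(lam, nrow = k)),
         gflat = unname(matrix(gflat, nrow = p * k)))
  }

  rates <- matrix(NA_real_, reps, length(methods),
                  dimnames = list(NULL, methods))
  kappas <- rep(NA_real_, reps)
  for (rep in seq_len(reps)) {
    train <- unlist(lapply(seq_len(n_groups), function(j) {
      feats_block(sim_block(rep, j, n_per_group, role = 1))
    }), recursive = FALSE)
    test <- unlist(lapply(seq_len(n_groups), function(j) {
      feats_block(sim_block(rep, j, test_per_group, role = 2))
    }), recursive = FALSE)
    tr <- to_mats(train)
    te <- to_mats(test)
    lam_bar <- t(rowsum(t(tr$lam), train_lab) / n_j)        # K x J
    Lambda <- t(lam_bar)
    Gflat <- rowsum(t(tr$gflat), train_lab) / n_j           # J x pK
    Gflat <- t(Gflat)                                       # pK x J

    for (mt in methods) {
      if (mt == "env") {
        sc <- score_env(te$lam, Lambda, selE)
      } else if (mt == "sca") {
        sc <- score_sca(te$gflat, Gflat, rowsS)
      } else if (mt == "envsca") {
        gam_tr <- array(tr$gflat, dim = c(p, k, ncol(tr$gflat)))
        tuned <- tune_core(tr$lam, gam_tr, train_lab, n_j, kappa_grid,
                           selE, selS = seq_len(k))
        kappas[rep] <- tuned$kappa
        ns <- norm_scores(te$lam, te$gflat, Lambda, Gflat, selE, rowsS)
        sc <- tuned$kappa * ns$env + (1 - tuned$kappa) * ns$sca
      } else {
        kind <- toupper(sub("smb_", "", mt))
        smes_tr <- lapply(train, `[[`, "sme")
        model <- smb_fit(smes_tr, train_lab, kind = kind)
        theta <- if (kind == "CH") tune_theta(smes_tr, train_lab) else NULL
        sc <- t(vapply(test, function(s) {
          vapply(seq_len(n_groups), function(j) {
            smb_distance(s$sme, model, j, theta = theta)
          }, numeric(1))
        }, numeric(n_groups)))
      }
      pred <- max.col(-sc, ties.method = "first")
      rates[rep, mt] <- 100 * mean(pred == test_lab)
    }
  }
  out <- tibble::tibble(
    case = if (is.null(m)) case else NA_integer_,
    m = m_states,
    n_per_group = n_per_group,
    t_length = t_length,
    method = methods,
    mean = unname(colMeans(rates)),
    sd = unname(apply(rates, 2, stats::sd)),
    mean_kappa = ifelse(methods == "envsca", mean(kappas), NA_real_),
    reps = reps)
  attr(out, "rates") <- rates
  attr(out, "kappas") <- kappas
  out
}
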