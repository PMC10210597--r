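# Lag-1 multinomial-logit simulator and study presets.
#
# Given the previous state's indicator vector Y_{t-1}, category
# probabilities are
#   p_l = exp(a_l' Y_{t-1}) / (1 + sum_l exp(a_l' Y_{t-1})),  l = 1..m-1,
#   p_m = 1 / (1 + sum_l exp(a_l' Y_{t-1})),
# with one regression vector a_l per non-reference category. Because the
# model conditions only on the previous state, it is exactly an m-state
# Markov chain; probabilities are precomputed per previous state with a
# numerically stable softmax and the chain is sampled by inverse CDF.

#' Transition matrix of the lag-1 multinomial-logit model
#'
#' Enumerates the category probabilities for every possible previous state
#' (each indicator vector, plus the zero vector for the reference state).
#'
#' @param alphas Numeric `(m - 1) x (m - 1)` matrix; row `l` is the
#'   regression vector for category `l`.
#' @return Row-stochastic `m x m` matrix; row `k` holds the next-state
#'   probabilities given current state `k` (reference state last).
#' @export
mlogit_transition_matrix <- function(alphas) {
  alphas <- as.matrix(alphas)
  if (nrow(alphas) != ncol(alphas)) {
    abort("`alphas` must be a square (m - 1) x (m - 1) matrix")
  }
  if (!all(is.finite(alphas))) abort("`alphas` entries must be finite")
  m <- nrow(alphas) + 1L
  pmat <- matrix(0, m, m)
  for (k in seq_len(m)) {
    eta <- c(if (k < m) alphas[, k] else numeric(m - 1), 0)
    eta <- eta - max(eta) # log-sum-exp guard
    pmat[k, ] <- exp(eta) / sum(exp(eta))
  }
  pmat
}

#' Simulate one categorical series from the multinomial-logit model
#'
#' The initial state is drawn uniformly and the first `burn_in` draws are
#' discarded so the retained stretch is approximately stationary.
#'
#' @inheritParams mlogit_transition_matrix
#' @param t_length Number of retained observations T (>= 1).
#' @param state_space Character vector of m state labels; default
#'   `c("c1", ..., "cm")`. The reference category is the last label.
#' @param burn_in Number of initial draws discarded (default 100).
#' @param seed Optional integer seed for this series.
#' @return Character vector of length `t_length`.
#' @export
simulate_series <- function(alphas, t_length, state_space = NULL,
                            burn_in = 100, seed = NULL) {
  if (t_length < 1) abort("`t_length` must be >= 1")
  if (burn_in < 0) abort("`burn_in` must be >= 0")
  pmat <- mlogit_transition_matrix(alphas)
  m <- nrow(pmat)
  if (is.null(state_space)) state_space <- paste0("c", seq_len(m))
  if (length(state_space) != m) {
    abort("`state_space` must have one label per category")
  }
  cum <- t(apply(pmat, 1, cumsum))
  state_space[sim_chain(cum, m, t_length, burn_in, seed)]
}

# integer-state chain sampler shared by the tidy simulator and the study
# driver; inverse-CDF draw per step from precomputed cumulative rows
sim_chain <- function(cum, m, t_length, burn_in, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- burn_in + t_length
  u <- stats::runif(n)
  x <- integer(n)
  st <- sample.int(m, 1)
  for (t in seq_len(n)) {
    st <- findInterval(u[t], cum[st, ]) + 1L
    x[t] <- st
  }
  x[(burn_in + 1):n]
}

#' Simulate a labeled collection of multinomial-logit series
#'
#' @param n Number of series.
#' @param t_length Length of each series.
#' @inheritParams simulate_series
#' @param id_prefix Prefix for generated series ids.
#' @return Long tibble with columns `series_id`, `time_index`, `state`.
#' @export
simulate_mlogit <- function(n, t_length, alphas, state_space = NULL,
                            burn_in = 100, seed = NULL, id_prefix = "s") {
  seeds <- derive_seeds(seed, n)
  width <- max(3L, nchar(as.character(n)))
  sims <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      series_id = sprintf("%s%0*d", id_prefix, width, i),
      time_index = seq_len(t_length),
      state = simulate_series(alphas, t_length, state_space,
                              burn_in = burn_in, seed = seeds[[i]]))
  })
  dplyr::bind_rows(sims)
}

# deterministic per-series substreams: results do not depend on the order
# in which series are generated
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.integer((as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483629)
}

#' Regression parameters of the simulation study presets
#'
#' The three study cases all use m = 4 categories. Cases 1 and 2 have two
#' groups; Case 3 has three. Case 1 groups differ in cycling speed
#' (envelope-dominated), Case 2 groups differ in traversals through
#' categories (scaling-dominated), Case 3 groups differ in both.
#'
#' @param case Case number: 1, 2, or 3.
#' @param group Group index within the case (1-based).
#' @return `(m - 1) x (m - 1)` matrix of regression vectors (rows).
#' @export
case_params <- function(case, group) {
  params <- list(
    `1` = list(
      rbind(c(1.2, 1, 1), c(1, 1.2, 1), c(1, 1, 1.2)),
      rbind(c(0.3, 1, 1), c(1, 0.3, 1), c(1, 1, 0.3))),
    `2` = list(
      rbind(c(1.2, 1, 1), c(1, 0.8, 1), c(1, 1, 0.4)),
      rbind(c(0.4, 1, 1), c(1, 0.8, 1), c(1, 1, 1.2))),
    `3` = list(
      rbind(c(0.3, 1, 1), c(1, 0.3, 1), c(1, 1, 0.3)),
      rbind(c(1.2, 1, 1), c(1, 0.8, 1), c(1, 1, 0.4)),
      rbind(c(1.25, 0.5, 1), c(-2, -0.75, -1), c(2, 0.75, -3))))
  key <- as.character(case)
  if (!key %in% names(params)) abort("`case` must be 1, 2, or 3")
  grp <- params[[key]]
  if (!group %in% seq_along(grp)) {
    abort(paste0("case ", case, " has groups 1..", length(grp)))
  }
  grp[[group]]
}

#' Number of groups in a study case
#' @inheritParams case_params
#' @return Integer group count.
#' @export
case_n_groups <- function(case) {
  if (!case %in% 1:3) abort("`case` must be 1, 2, or 3")
  if (case == 3) 3L else 2L
}

#' Regression parameters for the varying-m extension
#'
#' Extends the Case 1 design to an arbitrary number of categories m: each
#' regression vector is a vector of ones of length m - 1 whose l-th element
#' is replaced by 1.2 (group 1) or 0.3 (group 2).
#'
#' @param m Number of categories (>= 3).
#' @param group Group index, 1 or 2.
#' @return `(m - 1) x (m - 1)` matrix of regression vectors (rows).
#' @export
varying_m_params <- function(m, group) {
  if (m < 3) abort("`m` must be >= 3")
  if (!group %in% 1:2) abort("`group` must be 1 or 2")
  a <- matrix(1, m - 1, m - 1)
  diag(a) <- if (group == 1) 1.2 else 0.3
  a
}

#' Simulate a labeled data set from a study case
#'
#' @inheritParams case_params
#' @param n_per_group Series per group.
#' @param t_length Series length.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for series ids.
#' @return Long tibble with columns `series_id`, `time_index`, `state`,
#'   `group`; the state space (`c1..c4`, reference `c4`) is attached as
#'   attributes `state_space` and `ref_state`.
#' @examples
#' sim <- simulate_case(1, n_per_group = 3, t_length = 50, seed = 1)
#' dplyr::count(sim, group)
#' @export
simulate_case <- function(case, n_per_group, t_length, seed = NULL,
                          id_prefix = "s") {
  n_groups <- case_n_groups(case)
  state_space <- paste0("c", 1:4)
  parts <- lapply(seq_len(n_groups), function(j) {
    d <- simulate_mlogit(n_per_group, t_length, case_params(case, j),
                         state_space = state_space,
                         seed = if (is.null(seed)) NULL else seed + 131 * j,
                         id_prefix = paste0(id_prefix, "_g", j, "_"))
    d$group <- paste0("g", j)
    d
  })
  out <- dplyr::bind_rows(parts)
  structure(out, state_space = state_space, ref_state = "c4")
}

#' Synthetic hypnogram-like series
#'
#' Generates two groups of six-state sleep-stage-like series (states W, S1,
#' S2, S3, S4, R with Wake/Movement as the natural reference) from the
#' lag-1 multinomial-logit model, with heterogeneous lengths so that the
#' variable-length (periodogram interpolation) code path is exercised.
#' Group "A" has strongly self-persistent stages (slow cycling, more
#' low-frequency envelope power); group "B" cycles between stages faster.
#' This is a synthetic fixture: it emulates hypnogram structure (six
#' stages, stationary cycling, unequal recording lengths), not any real
#' patient population.
#'
#' @param n_per_group Series per group (length-2 vector or scalar).
#' @param length_range Inclusive range of series lengths (epochs).
#' @param seed Optional integer seed.
#' @return Long tibble with columns `series_id`, `time_index`, `state`,
#'   `group`, with `state_space`/`ref_state` attributes (reference `"W"`).
#' @export
synth_hypnograms <- function(n_per_group = c(12, 12),
                             length_range = c(420, 600), seed = NULL) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  if (any(n_per_group < 1)) abort("`n_per_group` must be positive")
  if (length(length_range) != 2 || length_range[1] < 8 ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be an increasing pair of lengths >= 8")
  }
  # reference state W last in simulator order; reported space starts with W
  sim_space <- c("S1", "S2", "S3", "S4", "R", "W")
  if (!is.null(seed)) set.seed(seed)
  lens <- lapply(n_per_group, function(n) {
    sample(length_range[1]:length_range[2], n, replace = TRUE)
  })
  alphas <- list(varying_m_params(6, 1), varying_m_params(6, 2))
  parts <- lapply(1:2, function(j) {
    seeds <- derive_seeds(if (is.null(seed)) NULL else seed + 977 * j,
                          n_per_group[j])
    dplyr::bind_rows(lapply(seq_len(n_per_group[j]), function(i) {
      tibble::tibble(
        series_id = sprintf("h_%s_%03d", c("A", "B")[j], i),
        time_index = seq_len(lens[[j]][i]),
        state = simulate_series(alphas[[j]], lens[[j]][i], sim_space,
                                seed = seeds[[i]]),
        group = c("A", "B")[j])
    }))
  })
  out <- dplyr::bind_rows(parts)
  structure(out, state_space = c("W", "S1", "S2", "S3", "S4", "R"),
            ref_state = "W")
}
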