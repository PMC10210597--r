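# Group features, distances, frequency selection, kappa tuning, and the
# fitted-classifier interface.

test_that("group features are plain averages of member features", {
  f1 <- feat_obj(c(1, 2), rbind(c(1, 0), c(0, 1)))
  f2 <- feat_obj(c(3, 4), rbind(c(0, 1), c(1, 0)))

  g_single <- group_features(list(f1), labels = "a")
  expect_equal(g_single$Lambda[1, ], c(1, 2))
  expect_equal(g_single$Gamma[, , 1], f1$gam)

  g_same <- group_features(list(f1, f1), labels = c("a", "a"))
  expect_equal(g_same$Lambda[1, ], f1$lam)
  expect_equal(g_same$Gamma[, , 1], f1$gam)

  # averaging scalings shrinks the norm (no renormalization)
  g_mix <- group_features(list(f1, f2), labels = c("a", "a"))
  expect_equal(g_mix$Gamma[, 1, 1], c(0.5, 0.5))
  expect_lt(sum(g_mix$Gamma[, 1, 1]^2), 1)

  f_short <- feat_obj(1, matrix(c(1, 0), 2, 1))
  expect_error(group_features(list(f1, f_short), c("a", "b")),
               "interpolate_features")
})

test_that("distances match hand computations and axioms", {
  expect_equal(dist_env(c(1, 2), c(1, 2)), 0)
  expect_equal(dist_env(c(1, 2), c(0, 0)), 5)
  expect_error(dist_env(c(1, 2), c(1, 2, 3)), "lengths differ")

  g <- diag(2)
  expect_equal(dist_sca(g, g), 0)
  expect_equal(dist_sca(g, matrix(0, 2, 2)), 2)     # K unit columns vs 0 -> K
  expect_equal(dist_sca(rbind(c(1, 0), c(0, 1)),
                        rbind(c(0, 1), c(1, 0))), 4)
  expect_error(dist_sca(g, matrix(0, 3, 3)), "shapes differ")

  # adaptive distance: hand-derived value at kappa = 0.5
  expect_equal(dist_envsca(c(1, 0), diag(2), c(0, 0), matrix(0, 2, 2),
                           kappa = 0.5), 1)
  # endpoint reductions
  lam <- c(2, 1); gam <- diag(2)
  glam <- c(1, 1); ggam <- matrix(0.5, 2, 2)
  expect_equal(dist_envsca(lam, gam, glam, ggam, 1),
               dist_env(lam, glam) / sum(lam^2))
  expect_equal(dist_envsca(lam, gam, glam, ggam, 0),
               dist_sca(gam, ggam) / 2)              # ||gam||_F^2 = K = 2
  expect_equal(dist_envsca(lam, gam, lam, gam, 0.37), 0)
  expect_error(dist_envsca(c(0, 0), gam, glam, ggam, 0.5), "degenerate")
  expect_error(dist_envsca(lam, gam, glam, ggam, 1.2), "kappa")
})

test_that("frequency selection ranks between-group differences (pairwise oracle)", {
  k <- 6
  set.seed(61)
  feats <- lapply(1:6, function(i) {
    feat_obj(runif(k), matrix(rnorm(2 * k), 2, k))
  })
  gf <- group_features(feats, labels = rep(c("a", "b", "c"), each = 2))

  # brute-force pair enumeration oracle for J = 3
  d_env <- numeric(k); d_sca <- numeric(k)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    d_env <- d_env + (gf$Lambda[pair[1], ] - gf$Lambda[pair[2], ])^2
    d_sca <- d_sca + colSums((gf$Gamma[, , pair[1]] - gf$Gamma[, , pair[2]])^2)
  }
  sel_all <- select_frequencies(gf, prop = 1)
  expect_equal(sel_all$env, 1:k)
  sel_half <- select_frequencies(gf, prop = 0.5)
  expect_equal(sel_half$env, sort(order(-d_env)[1:3]))
  expect_equal(sel_half$sca, sort(order(-d_sca)[1:3]))

  # two groups differing at a single frequency
  fa <- feat_obj(rep(1, 5), matrix(1, 2, 5))
  fb <- feat_obj(c(1, 1, 2, 1, 1), matrix(1, 2, 5))
  gf2 <- group_features(list(fa, fb), c("a", "b"))
  expect_equal(select_frequencies(gf2, prop = 1 / 5)$env, 3L)
  expect_error(select_frequencies(gf2, prop = 0), "prop")
})

test_that("kappa tuning is deterministic, honest-LOO, and handles edge grids", {
  feats <- case_feats(1, 1, 4, 80, seed = 100)
  feats <- c(feats, case_feats(1, 2, 4, 80, seed = 200))
  labs <- rep(c("a", "b"), each = 4)

  one <- tune_kappa(feats, labs, kappa_grid = 0.3)
  expect_equal(one$kappa, 0.3)

  t1 <- tune_kappa(feats, labs)
  t2 <- tune_kappa(feats, labs)
  expect_identical(t1, t2)                  # bit-for-bit reproducible
  expect_true(t1$kappa %in% seq(0, 1, 0.1))

  # indistinguishable groups: LOO rate near chance for every kappa
  same <- case_feats(1, 1, 6, 80, seed = 300)
  same <- c(same, case_feats(1, 1, 6, 80, seed = 400))
  t_same <- tune_kappa(same, rep(c("a", "b"), each = 6))
  expect_lt(max(t_same$grid_rates), 0.85)

  expect_error(tune_kappa(feats[1:3], c("a", "a", "b")), "at least 2")
})

test_that("adaptive classifier at kappa endpoints reproduces ENV / SCA rankings", {
  train <- simulate_case(3, n_per_group = 4, t_length = 100, seed = 9)
  test <- simulate_case(3, n_per_group = 5, t_length = 100, seed = 77,
                        id_prefix = "t")
  ss <- attr(train, "state_space")
  fit_k1 <- envsca_fit(train, state_space = ss, kappa = 1)
  fit_k0 <- envsca_fit(train, state_space = ss, kappa = 0)
  fit_env <- envsca_fit(train, state_space = ss, method = "env")
  fit_sca <- envsca_fit(train, state_space = ss, method = "sca")
  expect_equal(predict(fit_k1, test)$.pred_group,
               predict(fit_env, test)$.pred_group)
  expect_equal(predict(fit_k0, test)$.pred_group,
               predict(fit_sca, test)$.pred_group)
})

test_that("prediction assigns minimum-distance group; exact ties go low with a note", {
  model <- structure(list(
    method = "env", group_labels = c("a", "b"),
    Lambda = rbind(c(1, 1), c(5, 5)), selected_env = 1:2), class = "envsca_fit")
  mats <- list(lam = cbind(c(1.2, 1.1), c(3, 3)), gam = NULL)
  d <- envsca:::distance_matrix(model, mats)
  expect_equal(which.min(d[1, ]), 1L)
  expect_equal(d[2, 1], d[2, 2])            # constructed exact tie
  expect_message(
    out <- envsca:::predict_from_distances(d, model$group_labels, c("s1", "s2")),
    "lowest-index")
  expect_equal(out$.pred_group, c("a", "a"))
  expect_true(all(c("dist_a", "dist_b") %in% names(out)))
})

test_that("group-label permutation permutes predictions consistently", {
  train <- simulate_case(1, n_per_group = 4, t_length = 80, seed = 15)
  test <- simulate_case(1, n_per_group = 4, t_length = 80, seed = 55,
                        id_prefix = "t")
  ss <- attr(train, "state_space")
  swapped <- dplyr::mutate(train,
                           group = ifelse(group == "g1", "zz", "aa"))
  attr(swapped, "state_space") <- ss
  fit1 <- envsca_fit(train, state_space = ss, method = "env")
  fit2 <- envsca_fit(swapped, state_space = ss, method = "env")
  p1 <- predict(fit1, test)$.pred_group
  p2 <- predict(fit2, test)$.pred_group
  expect_equal(ifelse(p1 == "g1", "zz", "aa"), p2)
})

test_that("fitting validates labels, state space, and test series lengths", {
  train <- simulate_case(1, n_per_group = 3, t_length = 60, seed = 2)
  ss <- attr(train, "state_space")
  expect_error(envsca_fit(dplyr::select(train, -group), state_space = ss),
               "labels")
  fit <- envsca_fit(train, state_space = ss, method = "env")
  short <- simulate_case(1, n_per_group = 1, t_length = 40, seed = 3)
  expect_error(predict(fit, short), "shorter")
  # glance/tidy surface
  g <- glance(fit)
  expect_equal(g$n_train, 6)
  td <- tidy(fit)
  expect_named(td, c("group", "freq", "lambda", paste0("gamma_", 1:3)))
  expect_equal(nrow(td), 2 * fit$k)
})
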