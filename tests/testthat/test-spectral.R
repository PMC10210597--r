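# Indicator encoding, periodogram, smoothing, and eigen-features.

test_that("baseline encoding places indicators and zeroes the reference", {
  y <- encode_baseline(c("c1", "c2", "c3", "c3"), c("c1", "c2", "c3"))
  expect_equal(unname(y), rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0)))
  expect_equal(colnames(y), c("c1", "c2"))

  # series containing only the reference state
  expect_equal(unname(encode_baseline(rep("c3", 5), c("c1", "c2", "c3"))),
               matrix(0, 5, 2))

  # hypnogram convention: Wake/Movement as reference gives 5 columns
  states <- c("W", "S1", "S2", "S3", "S4", "R")
  y6 <- encode_baseline(c("S2", "W", "R"), states, ref_state = "W")
  expect_equal(ncol(y6), 5)
  expect_equal(colnames(y6), c("S1", "S2", "S3", "S4", "R"))
  expect_equal(unname(y6[2, ]), rep(0, 5))
  expect_equal(unname(y6[3, ]), c(0, 0, 0, 0, 1))

  expect_error(encode_baseline(c("a", "zz"), c("a", "b")), "zz")
  expect_error(encode_baseline(c("a", "zz"), c("a", "b")), "position 2")
  expect_error(encode_baseline("a", "a"), "m = 1|at least 2")
})

test_that("periodogram is rank-1 Hermitian PSD with exact conjugate symmetry", {
  y <- random_indicator(17, 3, seed = 5)
  pg <- periodogram_matrices(y)
  t_len <- 17
  for (s in c(1, 5, 16)) {
    i_s <- pg[, , s]
    expect_lt(max(abs(i_s - Conj(t(i_s)))), 1e-12)
    ev <- sort(eigen((i_s + Conj(t(i_s))) / 2, symmetric = TRUE)$values)
    expect_gt(ev[1], -1e-12)         # PSD
    expect_lt(ev[1], 1e-12)          # rank <= 1 for p = 2
  }
  expect_equal(pg[, , t_len - 3], Conj(pg[, , 3]))
})

test_that("constant series and added constants vanish at nonzero frequencies", {
  y <- encode_baseline(rep("c1", 12), c("c1", "c2", "c3"))
  expect_lt(max(abs(periodogram_matrices(y))), 1e-12)

  y2 <- random_indicator(16, 3, seed = 7)
  shifted <- sweep(y2, 2, c(2.5, -1.25), `+`)
  expect_lt(max(abs(periodogram_matrices(y2) - periodogram_matrices(shifted))),
            1e-9)
})

test_that("periodogram satisfies Parseval: mean ordinate = second moment", {
  y <- random_indicator(16, 3, seed = 11)
  pg <- periodogram_matrices(y)
  t_len <- nrow(y)
  i0 <- (colSums(y) %o% colSums(y)) / t_len       # excluded s = 0 ordinate
  lhs <- (apply(pg, c(1, 2), sum) + i0) / t_len
  rhs <- crossprod(y) / t_len                     # time-domain oracle
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("smoothing bandwidth, weights and boundary handling follow the rules", {
  expect_equal(resolve_bandwidth("sqrt", 100), 10)
  expect_equal(spectral_weights(0), 1)
  expect_equal(sum(spectral_weights(7)), 1)
  expect_equal(spectral_weights(2, "mdaniell"), c(0.5, 1, 1, 1, 0.5) / 4)
  expect_equal(spectral_weights(2, "daniell"), rep(1 / 5, 5))

  y <- random_indicator(32, 3, seed = 3)
  pg <- periodogram_matrices(y)

  # B = 0 is the identity smoother
  sm0 <- smooth_periodogram(pg, 32, bandwidth = 0)
  expect_equal(sm0$f_hat, pg[, , 1:15])

  # hand-computed Daniell window: f(5) = mean of I(2..8)
  sm <- smooth_periodogram(pg, 32, bandwidth = 3, kernel = "daniell")
  expect_equal(sm$f_hat[, , 5],
               apply(pg[, , 2:8], c(1, 2), mean), tolerance = 1e-12)

  # boundary: window at s = 1 reflects negative indices and drops s = 0
  oracle_s1 <- (Conj(pg[, , 2]) + Conj(pg[, , 1]) +
                  pg[, , 1] + pg[, , 2] + pg[, , 3] + pg[, , 4]) / 6
  expect_equal(sm$f_hat[, , 1], oracle_s1, tolerance = 1e-12)

  expect_error(smooth_periodogram(pg, 32, bandwidth = -1), "nonnegative")
  expect_error(smooth_periodogram(pg, 32, bandwidth = 15), "span")
  expect_error(smooth_periodogram(pg, 32, bandwidth = 2,
                                  weights = c(1, 1, 1)), "length")
  expect_error(smooth_periodogram(pg, 32, bandwidth = 1,
                                  weights = c(-0.5, 2, -0.5)), "nonnegative")
  expect_error(smooth_periodogram(pg, 32, bandwidth = 1,
                                  weights = c(0.1, 0.5, 0.4)), "symmetric")
})

test_that("smoothed estimates are Hermitian with PSD real part", {
  for (seed in 1:5) {
    y <- random_indicator(60 + 7 * seed, 4, seed = seed)
    sm <- smooth_periodogram(periodogram_matrices(y), nrow(y))
    for (s in seq_along(sm$freqs)) {
      f_s <- sm$f_hat[, , s]
      expect_lt(max(abs(f_s - Conj(t(f_s)))), 1e-10 * max(1, max(abs(f_s))))
      ev <- eigen((Re(f_s) + t(Re(f_s))) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-10 * sum(abs(diag(Re(f_s)))))
    }
  }
})

test_that("envelope and scalings match closed forms on 2x2 matrices", {
  sme <- sme_from_matrices(list(diag(c(3, 1)), rbind(c(2, 1), c(1, 2))))
  es <- envelope_scalings(sme)
  expect_equal(es$lam, c(3, 3))
  expect_equal(es$gam[, 1], c(1, 0))
  expect_equal(es$gam[, 2], c(1, 1) / sqrt(2))
  expect_equal(colSums(es$gam^2), rep(1, 2), tolerance = 1e-12)
  # Frobenius norm of gam is sqrt(K) when columns are unit vectors
  expect_equal(sqrt(sum(es$gam^2)), sqrt(2), tolerance = 1e-12)
})

test_that("envelope equals the quadratic-form maximum over random unit vectors", {
  f5 <- random_hpsd(5, seed = 21)
  sme <- sme_from_matrices(list(Re(f5)))
  es <- envelope_scalings(sme)
  best <- max_quad_random(Re(f5), seed = 22)  # random-search oracle
  expect_lt(best, es$lam[1] + 1e-10)
  expect_equal(best, es$lam[1], tolerance = 1e-3)
})

test_that("degenerate inputs are rejected or flagged", {
  bad <- sme_from_matrices(list(diag(2)))
  bad$f_hat[1, 1, 1] <- NaN
  expect_error(envelope_scalings(bad), "non-finite")
  expect_warning(envelope_scalings(sme_from_matrices(list(diag(c(2, 2))))),
                 "non-distinct")
})

test_that("feature pipeline yields K frequencies, flat white-noise envelope, and a period-2 peak", {
  set.seed(31)
  iid <- sample(c("a", "b", "c"), 2000, replace = TRUE)
  f <- features_for_series(iid, c("a", "b", "c"))
  expect_length(f$lam, 999)
  expect_lt(max(f$lam) / min(f$lam), 2)    # flat spectrum for white noise
  expect_true(all(f$lam > 0))

  # deterministic period-2 alternation: the spectral line sits exactly at
  # 0.5, so the smoothed envelope attains its maximum on the plateau of
  # frequencies whose window covers the line, including the one nearest 0.5
  alt <- rep(c("a", "b"), 200)
  # frequencies away from the line have an exactly-zero spectral matrix,
  # so the non-distinct-eigenvalue warning is expected here
  expect_warning(f2 <- features_for_series(alt, c("a", "b", "c")),
                 "non-distinct")
  k2 <- length(f2$lam)
  expect_equal(f2$lam[k2], max(f2$lam), tolerance = 1e-12)
  expect_true(all(f2$freqs[f2$lam > 0.99 * max(f2$lam)] > 0.4))
})

test_that("relabeling non-reference categories permutes scalings, envelope invariant", {
  set.seed(41)
  x <- sample(c("a", "b", "c", "d"), 300, replace = TRUE,
              prob = c(0.4, 0.3, 0.2, 0.1))
  f_ab <- features_for_series(x, c("a", "b", "c", "d"))
  f_ba <- features_for_series(x, c("b", "a", "c", "d"))
  expect_equal(f_ab$lam, f_ba$lam, tolerance = 1e-10)
  expect_equal(abs(f_ab$gam[c(2, 1, 3), ]), abs(f_ba$gam), tolerance = 1e-8)
})

test_that("variable-length features share the shortest grid; nested grids coincide", {
  set.seed(51)
  ss <- c("a", "b", "c")
  series <- lapply(c(100, 150, 200), function(t_len) {
    sample(ss, t_len, replace = TRUE)
  })
  feats <- interpolate_features(series, ss)
  expect_true(all(vapply(feats, function(f) length(f$lam), integer(1)) == 49))

  # grid-point coincidence: length-2T ordinate at index 2s equals the
  # interpolated ordinate at s/T exactly
  y_long <- encode_baseline(sample(ss, 128, replace = TRUE), ss)
  pg_long <- periodogram_matrices(y_long)
  pg_interp <- envsca:::pgram_on_grid(y_long, 64)
  expect_equal(pg_interp[, , 21], pg_long[, , 42], tolerance = 1e-12)

  # equal lengths: interpolation is a pass-through
  eq <- lapply(1:2, function(i) sample(ss, 80, replace = TRUE))
  expect_equal(interpolate_features(eq, ss)[[1]]$lam,
               features_for_series(eq[[1]], ss)$lam)
  expect_error(interpolate_features(eq[1], ss), "at least 2")
})

test_that("env_features returns a shared-grid tibble with gamma columns", {
  d <- synth_hypnograms(n_per_group = 2, length_range = c(60, 90), seed = 5)
  ef <- env_features(d, state_space = attr(d, "state_space"),
                     ref_state = attr(d, "ref_state"))
  expect_s3_class(ef, "tbl_df")
  expect_named(ef, c("series_id", "freq", "lambda", paste0("gamma_", 1:5)))
  expect_equal(dplyr::n_distinct(ef$freq),
               (min(dplyr::count(d, series_id)$n) - 1) %/% 2)
  expect_equal(attr(ef, "categories"), c("S1", "S2", "S3", "S4", "R"))
})
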