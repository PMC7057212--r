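test_that("delta_phi wraps correctly on the circle", {
  expect_equal(delta_phi(10, 350), 20)
  expect_equal(delta_phi(123.4, 123.4), 0)
  expect_equal(delta_phi(0, 180), 180)
  expect_equal(delta_phi(c(0, 90, 359), c(359, 271, 0)), c(1, 179, 1))
})

test_that("wMPD matches the weighted-average oracle and its analytic limits", {
  # hand case: weights (1,1,2) via F = (1,1,sqrt(2)) with unit foms
  cell <- c(10, 10, 10, 90, 90, 90)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  a <- phase_set(hkl, c(1, 1, sqrt(2)), rep(1, 3), c(0, 0, 0), cell, "P1", "a")
  b <- phase_set(hkl, c(1, 1, sqrt(2)), rep(1, 3), c(10, 20, 40), cell, "P1", "b")
  expect_equal(wmpd(a, b), 27.5)            # (10 + 20 + 2*40) / 4
  expect_identical(wmpd(a, a), 0)

  ps <- fx_random_ps(6000, seed = 1)
  expect_identical(wmpd(ps, ps), 0)
  qs <- fx_random_ps(6000, seed = 2)
  qs$hkl <- ps$hkl; qs$f <- ps$f            # shared indexing, random phases
  expect_equal(wmpd(ps, qs), 90, tolerance = 2 / 90)

  mismatched <- fx_random_ps(500, seed = 3)
  expect_error(wmpd(ps, mismatched), "indexed")
  z <- ps; z$fom <- rep(0, length(z$fom))
  expect_error(wmpd(z, ps), "weights")
})

test_that("mapCC limits and equivalence with the real-space map oracle", {
  ps <- fx_random_ps(6000, seed = 4)
  expect_equal(mapcc(ps, ps), 1, tolerance = 1e-12)
  qs <- fx_random_ps(6000, seed = 5)
  qs$hkl <- ps$hkl; qs$f <- ps$f
  expect_lt(abs(mapcc(ps, qs)), 0.05)

  # real-space oracle: correlate gridded Fourier syntheses of both sets
  cellp <- c(15, 16, 17, 90, 90, 90)
  hkl <- unique_reflections(cellp, "P1", 3.2)
  set.seed(6)
  n <- nrow(hkl)
  mk <- function(seed, id) {
    set.seed(seed)
    phase_set(hkl, sqrt(stats::rexp(n)), stats::runif(n, 0.3, 1),
              stats::runif(n, 0, 360), cellp, "P1", id)
  }
  a2 <- mk(7, "a2"); b2 <- mk(8, "b2")
  grid_map <- function(ps, g = 16L) {
    A <- array(0 + 0i, c(g, g, g))
    co <- ps$fom * ps$f * exp(1i * ps$phi * pi / 180)
    idx <- (ps$hkl %% g) + 1L
    neg <- ((-ps$hkl) %% g) + 1L
    for (i in seq_len(nrow(ps$hkl))) {
      A[idx[i, 1], idx[i, 2], idx[i, 3]] <-
        A[idx[i, 1], idx[i, 2], idx[i, 3]] + co[i]
      A[neg[i, 1], neg[i, 2], neg[i, 3]] <-
        A[neg[i, 1], neg[i, 2], neg[i, 3]] + Conj(co[i])
    }
    Re(stats::fft(A, inverse = TRUE))
  }
  expect_equal(mapcc(a2, b2), stats::cor(c(grid_map(a2)), c(grid_map(b2))),
               tolerance = 1e-3)
})

test_that("apply_origin_shift is the identity at 0 and inverts cleanly", {
  ps <- fx_random_ps(200, seed = 9)
  expect_equal(apply_origin_shift(ps, c(0, 0, 0))$phi, ps$phi)
  one <- phase_set(c(1, 0, 0), 1, 1, 0, c(10, 10, 10, 90, 90, 90), "P1")
  expect_equal(apply_origin_shift(one, c(0.5, 0, 0))$phi, 180)
  t <- c(0.21, 0.43, 0.65)
  back <- apply_origin_shift(apply_origin_shift(ps, t), -t)
  expect_lt(max(delta_phi(back$phi, ps$phi)), 1e-9)
})

test_that("discrete shift search recovers constructed shifts and matches the
           exhaustive oracle under noise", {
  sg <- space_group("P212121")
  truth <- fx_truth("P212121")
  expect_identical(best_shift_discrete(truth, truth, sg)$shift, c(0, 0, 0))

  set.seed(10)
  for (i in 1:5) {
    d_true <- sg$discrete_shifts[sample.int(8, 1), ]
    shifted <- apply_origin_shift(truth, -d_true)
    shifted$id <- "shifted"
    cmp <- best_shift_discrete(truth, shifted, sg)
    expect_lt(cmp$wmpd, 1e-6)
    expect_equal(shift_dist(cmp$shift, d_true, sg), 0, tolerance = 1e-9)
    expect_equal(cmp$mapcc, 1, tolerance = 1e-9)

    # independent oracle: plain loop over shifts through the public wmpd()
    noisy <- perturb_phases(shifted, 30, seed = 100 + i)
    cmp_n <- best_shift_discrete(truth, noisy, sg)
    oracle <- sapply(seq_len(8), function(j)
      wmpd(truth, apply_origin_shift(noisy, sg$discrete_shifts[j, ])))
    expect_equal(cmp_n$wmpd, min(oracle), tolerance = 1e-10)
    expect_equal(shift_dist(cmp_n$shift,
                            sg$discrete_shifts[which.min(oracle), ], sg), 0)
  }
  expect_error(best_shift_discrete(truth, truth, space_group("C2")), "polar")
})

test_that("sparse layer-1 search recovers polar shifts, wrap-aware", {
  sgc2 <- space_group("C2")
  base <- fx_truth("C2")
  t_true <- c(0.5, 0.237, 0)
  shifted <- apply_origin_shift(base, -t_true); shifted$id <- "s"
  cmp <- best_shift_sparse(base, shifted, sgc2)
  expect_lt(shift_dist(cmp$shift, t_true, sgc2), 0.002)
  expect_lt(cmp$wmpd, 0.5)

  self <- best_shift_sparse(base, base, sgc2)
  expect_lt(self$wmpd, 1e-4)
  expect_lt(shift_dist(self$shift, c(0, 0, 0), sgc2), 1e-3)

  # exact half-cell polar shift in P21 (wrap-around of the circular mean)
  sgp21 <- space_group("P21")
  b21 <- fx_truth("P21")
  t21 <- c(0, 0.5, 0)
  sh21 <- apply_origin_shift(b21, -t21); sh21$id <- "s21"
  cmp21 <- best_shift_sparse(b21, sh21, sgp21)
  expect_lt(shift_dist(cmp21$shift, t21, sgp21), 0.002)
  expect_lt(cmp21$wmpd, 0.5)
})

test_that("FFT search recovers continuous P1 shifts and agrees with sparse
           on random C2 pairs", {
  base <- fx_truth("P1")
  t_true <- c(0.13, 0.41, 0.77)
  shifted <- apply_origin_shift(base, -t_true); shifted$id <- "s"
  cmp <- best_shift_fft(base, shifted, "P1", grid = 64L)
  expect_lt(shift_dist(cmp$shift, t_true, space_group("P1")), 0.002)
  expect_lt(cmp$wmpd, 0.5)
  self <- best_shift_fft(base, base, "P1")
  expect_lt(self$wmpd, 1e-4)

  expect_error(best_shift_fft(base, base, "P1", grid = 48L), "power of two")
  expect_error(best_shift_fft(fx_truth("P212121"), fx_truth("P212121"),
                              "P212121"), "nonpolar")

  sgc2 <- space_group("C2")
  b <- fx_truth("C2")
  set.seed(31)
  for (i in 1:20) {
    t <- c(sample(c(0, .5), 1), stats::runif(1), sample(c(0, .5), 1))
    noisy <- perturb_phases(apply_origin_shift(b, -t), 20)
    noisy$id <- "n"
    cf <- best_shift_fft(b, noisy, sgc2)
    cs <- best_shift_sparse(b, noisy, sgc2)
    expect_lt(shift_dist(cf$shift, cs$shift, sgc2), 0.005)
    expect_lt(abs(cf$wmpd - cs$wmpd), 0.1)
  }
})

test_that("best wMPD is symmetric and invariant under common origin moves", {
  sg <- space_group("P212121")
  truth <- fx_truth("P212121")
  set.seed(41)
  for (i in 1:5) {
    noisy <- perturb_phases(apply_origin_shift(
      truth, -sg$discrete_shifts[sample.int(8, 1), ]), 35)
    noisy$id <- "n"
    ab <- best_origin_shift(truth, noisy, sg)$wmpd
    ba <- best_origin_shift(noisy, truth, sg)$wmpd
    expect_lt(abs(ab - ba), 0.1)
    # common shift applied to both leaves the best wMPD unchanged
    d <- sg$discrete_shifts[sample.int(8, 1), ]
    ab2 <- best_origin_shift(apply_origin_shift(truth, d),
                             apply_origin_shift(noisy, d), sg)$wmpd
    expect_equal(ab, ab2, tolerance = 1e-9)
  }
})

test_that("mean wMPD grows monotonically with phase noise", {
  truth <- fx_truth("P212121")
  sg <- space_group("P212121")
  sigmas <- c(0, 15, 30, 50, 70, 90)
  means <- vapply(sigmas, function(s) {
    mean(vapply(1:4, function(r) {
      noisy <- perturb_phases(truth, s, seed = 1000 * s + r)
      noisy$id <- "n"
      best_origin_shift(truth, noisy, sg)$wmpd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 1e-9)
})

test_that("auto dispatch picks a valid algorithm per symmetry", {
  expect_identical(best_origin_shift(fx_truth("P212121"), fx_truth("P212121"),
                                     "P212121")$algorithm, "discrete")
  expect_identical(best_origin_shift(fx_truth("P1"), fx_truth("P1"),
                                     "P1")$algorithm, "fft")
  expect_identical(best_origin_shift(fx_truth("C2"), fx_truth("C2"),
                                     "C2")$algorithm, "sparse")
})
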