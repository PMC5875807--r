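test_that("spin fractions follow the penetration-distance decomposition", {
  sq <- fx_seq(TR = 1.2, TE = 0.015, Thk = 0.5)

  # static spins
  f0 <- spin_fractions(0, sq)
  expect_equal(unlist(f0[c("alpha", "beta", "dz_T1", "dz_T2")]),
               c(alpha = 0, beta = 1, dz_T1 = 0, dz_T2 = 0))

  # direct evaluation: dz_T1 = v*(TR - TE)
  f <- spin_fractions(0.1, sq)
  expect_equal(f$dz_T1, 0.1185)
  expect_equal(f$alpha, 0.237)
  expect_equal(f$dz_T2, 0.0015)
  expect_false(f$clamped)

  # full replacement at the saturation boundary (TE << TR)
  sq2 <- fx_seq(TR = 1.2, TE = 1e-5, Thk = 0.5)
  fb <- spin_fractions(0.5 / 1.2, sq2)
  expect_equal(fb$alpha, 1, tolerance = 1e-4)
  expect_equal(fb$beta, 0, tolerance = 1e-4)

  # clamping: most recent inflow (dz_T2) takes precedence, alpha reduced
  fc <- spin_fractions(2 * sq$Thk / sq$TR, sq)
  expect_true(fc$clamped)
  expect_equal(fc$dz_T2, 2 * sq$Thk / sq$TR * sq$TE)
  expect_equal(fc$dz_T1, sq$Thk - fc$dz_T2)
  expect_equal(fc$beta, 0)
  expect_equal(fc$alpha + fc$beta + fc$dz_T2 / sq$Thk, 1)

  expect_error(spin_fractions(-0.1, sq), "non-negative")
})

test_that("inflow signal reduces to the two-pool limits", {
  ti <- fx_tissue(); sq <- fx_seq(); g <- fx_geom(sq)

  # static limit
  s0 <- inflow_signal(0, ti, sq, g)
  expect_equal(s0, g$Afov * g$kc * sq$Thk *
    (ti$M0m * exp(-sq$TE / ti$T2m) * (1 - exp(-sq$TR / ti$T1m)) +
     ti$M0s * exp(-sq$TE / ti$T2s) * (1 - exp(-sq$TR / ti$T1s))))

  # Boltzmann equilibrium limit: TR -> inf (TE negligible) removes flow
  # dependence; every finite v is then formally beyond the slow-flow bound
  sqi <- fx_seq(TR = 1000, TE = 1e-6)
  v <- c(0, 0.1, 0.3)
  si <- suppressWarnings(inflow_signal(v, ti, sqi, voxel_geom(sqi)))
  expect_equal(si, rep(g$Afov * g$kc * sqi$Thk *
    (ti$M0m * exp(-sqi$TE / ti$T2m) + ti$M0s * exp(-sqi$TE / ti$T2s)), 3),
    tolerance = 1e-5)

  expect_warning(inflow_signal(2 * sq$Thk / sq$TR, ti, sq, g), "slow-flow bound")
})

test_that("signal decomposition via spin fractions matches the closed form", {
  set.seed(41)
  for (i in 1:25) {
    d <- fx_draw(); g <- voxel_geom(d$seq)
    v <- runif(1, 0, 0.9 * d$seq$Thk / d$seq$TR)
    fr <- spin_fractions(v, d$seq)
    via_fracs <- g$Afov * g$kc * d$seq$Thk *
      (fr$alpha * d$tissue$M0m * exp(-d$seq$TE / d$tissue$T2m) +
       fr$beta * d$tissue$M0m * (1 - exp(-d$seq$TR / d$tissue$T1m)) *
         exp(-d$seq$TE / d$tissue$T2m) +
       d$tissue$M0s * exp(-d$seq$TE / d$tissue$T2s) *
         (1 - exp(-d$seq$TR / d$tissue$T1s)))
    expect_equal(inflow_signal(v, d$tissue, d$seq, g), via_fracs,
                 tolerance = 1e-12)
  }
})

test_that("flip form and generic inflow form are algebraically identical in the slow-flow regime", {
  set.seed(42)
  for (i in 1:25) {
    d <- fx_draw(); g <- voxel_geom(d$seq)
    v <- runif(5, 0, d$seq$Thk / d$seq$TR)
    expect_equal(flip_signal(v, d$tissue, d$seq, g),
                 inflow_signal(v, d$tissue, d$seq, g), tolerance = 1e-12)
  }
})

test_that("flip minus flop reproduces the closed-form difference law", {
  set.seed(43)
  for (i in 1:25) {
    d <- fx_draw(); g <- voxel_geom(d$seq)
    v <- runif(5, 0, d$seq$Thk / d$seq$TR)
    expect_equal(flip_signal(v, d$tissue, d$seq, g) -
                   flop_signal(v, d$tissue, d$seq, g),
                 flipflop_difference(v, d$tissue, d$seq, g), tolerance = 1e-12)
  }
})

test_that("flop signal loses a v*NS*TE slab and is flow-insensitive as NS*TE -> 0", {
  ti <- fx_tissue(); sq <- fx_seq(NS = 2L, TE = 0.015); g <- fx_geom(sq)
  # moving-spin slab reduced by 1.5 um at v = 0.05 mm/s
  slab_loss <- (flop_signal(0, ti, sq, g) - flop_signal(0.05, ti, sq, g)) /
    (g$Afov * g$kc * ti$M0m * exp(-sq$TE / ti$T2m) * (1 - exp(-sq$TR / ti$T1m)))
  expect_equal(slab_loss, 0.0015)
  expect_equal(flop_signal(0, ti, sq, g), flip_signal(0, ti, sq, g))

  sq0 <- fx_seq(TE = 1e-8)
  expect_equal(flop_signal(c(0, 0.1, 0.3), ti, sq0, fx_geom(sq0)),
               rep(flop_signal(0, ti, sq0, fx_geom(sq0)), 3), tolerance = 1e-7)
})

test_that("difference signal is odd, static-blind and linear below saturation", {
  set.seed(44)
  for (i in 1:20) {
    d <- fx_draw(); g <- voxel_geom(d$seq)
    v <- runif(1, 0, 0.7 * d$seq$Thk / d$seq$TR)  # v + h stays below saturation

    # oddness and exact zero at v = 0
    expect_identical(flipflop_difference(0, d$tissue, d$seq, g), 0)
    expect_equal(flipflop_difference(-v, d$tissue, d$seq, g),
                 -flipflop_difference(v, d$tissue, d$seq, g))

    # independence of every static-pool parameter (exact cancellation)
    t2 <- tissue_params(d$tissue$M0m, d$tissue$M0s * 3 + 0.1,
                        d$tissue$T1m, d$tissue$T1s * 2,
                        d$tissue$T2m, d$tissue$T2s * 0.9)
    expect_identical(flipflop_difference(v, d$tissue, d$seq, g),
                     flipflop_difference(v, t2, d$seq, g))

    # exact linearity: vanishing second difference
    h <- v / 3
    s <- flipflop_difference(c(v - h, v, v + h), d$tissue, d$seq, g)
    expect_equal(s[3] - 2 * s[2] + s[1], 0, tolerance = 1e-12 * abs(s[2]))
  }
})

test_that("simplified difference converges to the exact law as NS*TE/TR -> 0", {
  ti <- fx_tissue(); v <- 0.1
  # at NS*TE/TR = 0.025 the two agree within 3%
  sq <- fx_seq(TR = 1.2, TE = 0.015, NS = 2L)
  g <- fx_geom(sq)
  rel <- abs(flipflop_difference(v, ti, sq, g) / flipflop_simplified(v, ti, sq, g) - 1)
  expect_lt(rel, 0.03)
  # shrinking TE tightens the agreement below the NS*TE/TR bound
  for (TE in c(0.01, 0.003, 0.001)) {
    sqe <- fx_seq(TR = 1.2, TE = TE, NS = 2L)
    rel_e <- abs(flipflop_difference(v, ti, sqe, fx_geom(sqe)) /
                   flipflop_simplified(v, ti, sqe, fx_geom(sqe)) - 1)
    expect_lt(rel_e, sqe$NS * TE / sqe$TR)
    expect_lt(rel_e, rel)
    rel <- rel_e
  }
})

test_that("distributed-TR forms are mutually consistent", {
  set.seed(45)
  for (i in 1:20) {
    ti <- fx_tissue(M0s = runif(1, 0, 1))
    sq <- seq_params(TR = runif(1, 1, 3), TE = 0.005, Thk = 0.5,
                     NS = sample(2:4, 1), distributed = TRUE)
    g <- voxel_geom(sq)
    v <- runif(3, 0, 0.9 * sq$Thk / sq$TR)
    # difference of the two orderings equals the closed-form difference
    expect_equal(flip_signal_distributed(v, ti, sq, g) -
                   flop_signal_distributed(v, ti, sq, g),
                 flipflop_distributed(v, ti, sq, g), tolerance = 1e-12)
    expect_identical(flipflop_distributed(0, ti, sq, g), 0)
  }
})

test_that("distributed difference reduces to the concentrated kernel at NS = 1", {
  ti <- fx_tissue()
  sq1 <- seq_params(TR = 1.2, TE = 0.005, Thk = 0.5, NS = 1L, distributed = TRUE)
  g <- voxel_geom(sq1)
  v <- c(-0.2, 0.05, 0.1)
  expect_equal(flipflop_distributed(v, ti, sq1, g),
               g$Afov * g$kc * ti$M0m * exp(-sq1$TE / ti$T2m) *
                 v * sq1$TR * exp(-sq1$TR / ti$T1m))
})

test_that("flip signal is increasing below saturation, then plateaus", {
  ti <- fx_tissue(); sq <- fx_seq(); g <- fx_geom(sq)
  vsat <- sq$Thk / sq$TR
  v_lo <- seq(0, vsat, length.out = 20)
  expect_true(all(diff(flip_signal(v_lo, ti, sq, g)) > 0))
  s_hi <- suppressWarnings(flip_signal(c(vsat, 1.5 * vsat, 2 * vsat), ti, sq, g))
  # beyond the bound only the small TE-window loss remains
  expect_lt(max(abs(s_hi - s_hi[1])) / s_hi[1], 2 * sq$TE / sq$TR)
})

test_that("parameter records validate and round-trip through JSON", {
  expect_error(seq_params(TR = 1, TE = 1.5, Thk = 0.5), "TE must be smaller")
  expect_error(seq_params(TR = 0.1, TE = 0.06, Thk = 0.5, NS = 2), "NS\\*TE < TR")
  expect_warning(tissue_params(1, 1, T1m = 1, T1s = 1, T2m = 2, T2s = 0.05),
                 "implausible")
  expect_warning(seq_params(TR = 1, TE = 0.2, Thk = 0.5, NS = 2,
                            distributed = TRUE), "TE << TR/NS")

  sq <- fx_seq(AVG = 4L)
  expect_equal(params_from_json(params_to_json(sq)), sq)
  ti <- fx_tissue()
  expect_equal(params_from_json(params_to_json(ti)), ti)
})
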