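test_that("subtraction cancels static regions and flags opposite flows", {
  ph <- bench_preset(0.1, seed = 21L)
  pair <- suppressMessages(render_pair(ph))
  fimg <- subtract(pair)

  # identical images give an all-zero difference
  same <- pair; same$flop <- same$flip
  expect_true(all(subtract(same)$data == 0))

  # noisy flow-free border: mean within 3 standard errors of zero
  border <- as.numeric(fimg$data[1:12, ])
  se <- stats::sd(border) / sqrt(length(border))
  expect_lt(abs(mean(border)), 3 * se)

  # noiseless difference map equals the closed-form difference
  ph0 <- bench_preset(0.1, noise_sigma = 0)
  f0 <- subtract(suppressMessages(render_pair(ph0)))
  ras <- flipflow:::rasterize_phantom(ph0)
  interior <- ras$occ == 1
  expect_equal(f0$data[interior],
               flipflop_difference(ras$vin[interior], ph0$lumen, ph0$seq,
                                   voxel_geom(ph0$seq)),
               tolerance = 1e-12)
})

test_that("segmentation finds the two tubes with opposite signs", {
  ph <- bench_preset(0.1, seed = 22L)
  fimg <- subtract(suppressMessages(render_pair(ph)))
  seg <- segment_flow(fimg)
  expect_equal(nrow(seg$table), 2)
  expect_equal(sort(sign(seg$table$mean_signal)), c(-1, 1))
  # region sizes comparable to the tube disc area (~ pi * (R/dx)^2 px)
  px_area <- pi * (1.5 / (20 / 128))^2
  expect_true(all(seg$table$n > 0.6 * px_area & seg$table$n < 1.3 * px_area))
  # labels partition the mask
  expect_equal(sum(seg$labels > 0), sum(seg$table$n))

  # all-noise image: empty segmentation with a warning
  quiet <- fimg
  set.seed(1)
  quiet$data <- matrix(stats::rnorm(64 * 64), 64, 64)
  expect_warning(s0 <- segment_flow(quiet, threshold_sigmas = 6), "empty")
  expect_equal(nrow(s0$table), 0)
})

test_that("8-connected labelling separates diagonal-touching from disjoint regions", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE   # diagonal chain: one component
  m[7, 7] <- TRUE                          # isolated
  lab <- flipflow:::label_components(m)
  expect_equal(length(unique(lab[lab > 0])), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[3, 3], lab[4, 4])
  expect_false(lab[7, 7] == lab[2, 2])
})

test_that("noiseless bench series recovers the generator peak velocity within 1%", {
  ph <- bench_preset(0.1, noise_sigma = 0)
  ser <- suppressMessages(render_series(ph, bench_tr_series()))
  fit <- fit_vmax(ser, t1m = 2.46)
  expect_equal(fit$vmax_hat, 0.2, tolerance = 0.01)
  expect_true(fit$diagnostics$identifiable)
  expect_equal(fit$recommended_TR_bound, ph$seq$Thk / fit$vmax_hat)

  # methods on the fitted object
  expect_named(coef(fit), c("vmax", "scale"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fit$data$signal - fitted(fit), residuals(fit))
  expect_output(print(fit), "vmax_hat")
  expect_output(print(summary(fit)), "identifiable")
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(length(bench_tr_series()), 4L))
})

test_that("an all-untruncated TR series is flagged as non-identifiable", {
  ph <- bench_preset(0.1, noise_sigma = 0)
  ser <- suppressMessages(render_series(ph, c(0.1, 0.4, 0.8, 1.2, 1.6, 2.0)))
  expect_warning(fit <- fit_vmax(ser, t1m = 2.46), "confounded")
  expect_false(fit$diagnostics$identifiable)
})

test_that("an all-zero ROI yields vmax 0", {
  df <- data.frame(TR = c(0.5, 1, 2, 4), signal = c(0, 0, 0, 0))
  fit <- fit_vmax(df, t1m = 2.46, thk = 0.5, variant = "case1_simplified")
  expect_equal(fit$vmax_hat, 0)
  expect_equal(fit$scale_hat, 0)
})

test_that("opposite tubes give opposite-sign ROI means and the same speed estimate", {
  ph <- bench_preset(0.1, seed = 23L)
  ser <- suppressMessages(render_series(ph, bench_tr_series()))
  k_ref <- which.min(abs(ser$TR - 1.23))
  seg <- segment_flow(subtract(ser$pairs[[k_ref]]))
  expect_equal(sort(sign(seg$table$mean_signal)), c(-1, 1))
  fits <- lapply(seg$table$id, function(i)
    fit_vmax(ser, roi = seg$labels == i, t1m = 2.46))
  v <- vapply(fits, function(f) f$vmax_hat, numeric(1))
  expect_equal(v[1], v[2], tolerance = 0.05)
  expect_equal(median(v), 0.2, tolerance = 0.1)
})

test_that("static-pool changes do not move the velocity estimate", {
  base <- bench_preset(0.1, noise_sigma = 0)
  doubled <- flow_phantom(base$seq, base$tubes, base$lumen,
                          tissue_params(M0m = 0, M0s = 2 * base$background$M0s,
                                        T1m = 2.46, T1s = 1, T2m = 2, T2s = 0.05),
                          noise_sigma = 0, seed = base$seed)
  f1 <- fit_vmax(suppressMessages(render_series(base, bench_tr_series())),
                 t1m = 2.46)
  f2 <- fit_vmax(suppressMessages(render_series(doubled, bench_tr_series())),
                 t1m = 2.46)
  expect_lt(abs(f2$vmax_hat - f1$vmax_hat) / f1$vmax_hat, 0.01)
})

test_that("the truncated model explains the high-TR bend that the untruncated model cannot", {
  # peak velocity = 2 * Thk / max(TR): half the disc is clipped at the
  # longest TR, so the TR curve bends away from the linear-in-velocity shape
  ph <- bench_preset(0.1, noise_sigma = 0)
  ser <- suppressMessages(render_series(ph, bench_tr_series()))
  fit <- fit_vmax(ser, t1m = 2.46)
  df <- fit$data
  kern <- flipflow:::fit_kernel(df$TR, 2.46, ph$seq$NS, ph$seq$TE, "case1")
  ssr_full <- sum(residuals(fit)^2)
  x0 <- df$TR * kern  # untruncated model: apparent mean constant in TR
  s0 <- sum(df$signal * x0) / sum(x0^2)
  ssr_untrunc <- sum((df$signal - s0 * x0)^2)
  expect_gt(ssr_untrunc, 10 * ssr_full)
  # and the misfit concentrates at the truncated (high-TR) end
  res0 <- df$signal - s0 * x0
  trunc_tr <- df$TR > fit$recommended_TR_bound
  expect_gt(max(abs(res0[trunc_tr])), max(abs(residuals(fit))))
})

test_that("calibration turns the subtraction image into a velocity map", {
  ph <- bench_preset(0.1, noise_sigma = 0)
  ser <- suppressMessages(render_series(ph, bench_tr_series()))
  fit <- fit_vmax(ser, t1m = 2.46)
  k_ref <- which.min(abs(ser$TR - 1.23))
  cal <- calibrate(subtract(ser$pairs[[k_ref]]), fit)
  expect_equal(cal$units, "mm/s")
  ras <- flipflow:::rasterize_phantom(ph)
  interior <- ras$occ == 1 & abs(ras$vin) > 0.05
  # velocity map is proportional to the truth: shape recovered exactly
  ratio <- cal$data[interior] / ras$vin[interior]
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-6)
  # absolute level carries the documented partial-volume dilution of the
  # fitted amplitude (edge pixels lower the ROI mean): ~10%, not more
  expect_equal(mean(ratio), 1, tolerance = 0.12)
  expect_equal(cal$calibration$n_saturated, 0)
})

test_that("saturation-recovery T1 fit recovers the liquid T1 from rendered statics", {
  # no flow: pure static lumen signal, with bench-level noise averaged
  # over the tube ROI
  ph <- bench_preset(0, noise_sigma = 5e-5, seed = 9L)
  TRs <- c(0.3, 0.6, 1.2, 2.4, 4.8)
  ser <- suppressMessages(render_series(ph, TRs))
  ras <- flipflow:::rasterize_phantom(ph)
  mask <- ras$occ == 1
  df <- data.frame(TR = TRs, signal = vapply(ser$pairs,
    function(p) mean(p$flip[mask]), numeric(1)))
  est <- t1_fit(df)
  expect_equal(est$T1, 2.46, tolerance = 1e-2)
  expect_error(t1_fit(df[1:2, ]), ">= 3 rows")
})
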