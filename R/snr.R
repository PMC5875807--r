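#' Noise and acquisition-time budget
#'
#' @param sigma0 Composite noise amplitude: the
#'   `F*sqrt(4*k*T*Rtot*BW)` lump of amplifier noise figure, thermal
#'   noise and bandwidth, in signal units.
#' @param Tacq Total acquisition time budget (s); averaging is
#'   `AVG = Tacq/TR`, so SNR scales as `sqrt(Tacq/TR)` per unit signal.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma0, Tacq) {
  if (sigma0 <= 0 || Tacq <= 0) stop("sigma0 and Tacq must be positive")
  structure(list(sigma0 = sigma0, Tacq = Tacq), class = "noise_params")
}

#' Fixed-time SNR of the flip-flop difference signal
#'
#' `SNR = Afov * kc * v * M0m * exp(-TE/T2m) * TR * exp(-TR/T1m) *
#' sqrt(Tacq/TR) / sigma0`: the simplified difference signal times the
#' square root of the number of averages that fit in the time budget,
#' over the composite noise amplitude. Proportional to `v` and to
#' `sqrt(Tacq)`; as a function of TR it rises linearly, is damped by
#' longitudinal recovery, and peaks at `TR = T1m/2`.
#'
#' @param v Velocity (mm/s), vectorized.
#' @param tissue A [tissue_params()] object.
#' @param seq A [seq_params()] object (its TR and TE are used).
#' @param geom A [voxel_geom()] object.
#' @param noise A [noise_params()] object.
#' @return Dimensionless SNR, same length as `v`.
#' @export
snr <- function(v, tissue, seq, geom, noise) {
  stopifnot(inherits(noise, "noise_params"))
  abs(flipflop_simplified(v, tissue, seq, geom)) *
    sqrt(noise$Tacq / seq$TR) / noise$sigma0
}

#' Optimal repetition time for the flip-flop sequence
#'
#' The TR maximizing the fixed-time SNR of the difference signal. The
#' closed form is `TR = T1m/2`; a numerical argmax of the SNR expression
#' over `TR` in `(0, 5*T1m]` is computed alongside and agreement within
#' 0.1% is asserted. The optimum does not depend on `v`, `sigma0`,
#' `Tacq`, `kc` or `Afov`, which enter as pure scale factors.
#'
#' @param T1m Longitudinal relaxation time of the moving spins (s).
#' @return List with `TR_opt` (the closed form `T1m/2`, s),
#'   `TR_numeric` (the numeric argmax), and `rel_diff`.
#' @examples
#' optimal_tr(2.46)$TR_opt  # 1.23 s
#' @export
optimal_tr <- function(T1m) {
  if (T1m <= 0) stop("T1m must be positive")
  closed <- T1m / 2
  # objective proportional to sqrt(TR) * exp(-TR/T1m); scale factors dropped
  obj <- function(TR) sqrt(TR) * exp(-TR / T1m)
  num <- stats::optimize(obj, c(1e-9, 5 * T1m), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)$maximum
  rel <- abs(num - closed) / closed
  stopifnot(rel <= 1e-3)
  list(TR_opt = closed, TR_numeric = num, rel_diff = rel)
}

#' Sampled SNR-versus-TR design curve
#'
#' Convenience for sequence design and for the command-line `design`
#' report: samples the fixed-time SNR over a TR range (normalized to its
#' maximum, so no tissue amplitude or noise level is needed) and reports
#' the optimum.
#'
#' @param T1m Moving-pool T1 (s).
#' @param TE Echo time (s), held fixed (only TR is optimized).
#' @param T2m Moving-pool T2 (s); with fixed TE this is a constant
#'   factor and does not move the optimum.
#' @param n Number of TR samples.
#' @return List with `TR_opt`, `TR_numeric`, and a data.frame `curve`
#'   with columns `TR` and `snr_rel`.
#' @export
design_report <- function(T1m, TE = 0.015, T2m = 2, n = 101) {
  opt <- optimal_tr(T1m)
  TR <- seq(5 * T1m / n, 5 * T1m, length.out = n)
  s <- sqrt(TR) * exp(-TR / T1m) * exp(-TE / T2m)
  list(TR_opt = opt$TR_opt, TR_numeric = opt$TR_numeric,
       curve = data.frame(TR = TR, snr_rel = s / max(s)))
}
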