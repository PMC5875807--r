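#' Spin fractions of a slice crossed by slow flow
#'
#' Decomposes the spin content of an excited slice of thickness `Thk`
#' after one repetition period, for plug displacement at speed `v`:
#' `dz_T1 = v*(TR - TE)` is the penetration distance of fully magnetized
#' spins that entered between the previous echo and the next excitation,
#' `dz_T2 = v*TE` the distance of spins that entered between excitation
#' and echo (detected with essentially zero signal), `alpha = dz_T1/Thk`
#' the fully magnetized inflow fraction and
#' `beta = (Thk - dz_T1 - dz_T2)/Thk` the fraction of spins that stayed
#' in the slice and carry saturation-recovery magnetization.
#'
#' When `v*TR > Thk` the penetration distances exceed the slice: the most
#' recent inflow (`dz_T2`) takes precedence, `dz_T1` fills the remainder,
#' and `beta` clamps at zero. `alpha + beta + dz_T2/Thk = 1` always.
#'
#' @param v Non-negative speed (mm/s); may be a vector. Direction is
#'   handled by callers through the sign of the velocity field.
#' @param seq A [seq_params()] object.
#' @return A data.frame with columns `alpha`, `beta`, `dz_T1`, `dz_T2`
#'   (mm) and logical `clamped`.
#' @examples
#' s <- seq_params(TR = 1.2, TE = 0.015, Thk = 0.5)
#' spin_fractions(0.1, s)  # alpha = 0.237
#' @export
spin_fractions <- function(v, seq) {
  stopifnot(inherits(seq, "seq_params"))
  if (any(v < 0)) stop("v must be non-negative; handle direction by sign at the caller")
  Thk <- seq$Thk
  dz_T2 <- pmin(v * seq$TE, Thk)
  dz_T1 <- pmin(v * (seq$TR - seq$TE), Thk - dz_T2)
  beta <- pmax((Thk - dz_T1 - dz_T2) / Thk, 0)
  data.frame(alpha = dz_T1 / Thk, beta = beta,
             dz_T1 = dz_T1, dz_T2 = dz_T2,
             clamped = v * seq$TR > Thk)
}

# --- internal cores: vectorized over v, no warnings ----------------------

# static (two-pool, v = 0) contribution common to every expression
.static_term <- function(tissue, seq) {
  tissue$M0s * exp(-seq$TE / tissue$T2s) * seq$Thk *
    (1 - exp(-seq$TR / tissue$T1s))
}

# generic inflow signal from (possibly clamped) spin fractions; reduces to
# the verbatim slow-flow expression when no clamping occurs
.inflow_core <- function(v, tissue, seq, geom) {
  fr <- spin_fractions(v, seq)
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  moving <- tissue$M0m * e2m *
    (fr$dz_T1 + (seq$Thk - fr$dz_T1 - fr$dz_T2) * (1 - E1m))
  geom$Afov * geom$kc * (moving + .static_term(tissue, seq))
}

.flop_core <- function(v, tissue, seq, geom) {
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  moving <- tissue$M0m * e2m * pmax(seq$Thk - v * seq$NS * seq$TE, 0) * (1 - E1m)
  geom$Afov * geom$kc * (moving + .static_term(tissue, seq))
}

.warn_saturation <- function(v, seq, what) {
  if (any(v * seq$TR > seq$Thk))
    warning(sprintf("%s: v exceeds the slow-flow bound Thk/TR = %g mm/s; evaluating with clamped spin fractions",
                    what, seq$Thk / seq$TR))
}

#' Voxel signal of an inflow-sensitive slice (generic form)
#'
#' The spin-echo voxel signal of a slice with fresh inflow at speed `v`,
#' expressed through the spin fractions: fully magnetized inflow,
#' saturation-recovering resident spins and the static pool. In the
#' slow-flow regime `v <= Thk/TR` this equals (verbatim)
#' `Afov*kc*(M0m*exp(-TE/T2m)*(v*(TR-TE) + (Thk - v*TR)*(1 - exp(-TR/T1m)))
#'  + M0s*exp(-TE/T2s)*Thk*(1 - exp(-TR/T1s)))`.
#'
#' @param v Non-negative speed (mm/s), vectorized.
#' @param tissue A [tissue_params()] object.
#' @param seq A [seq_params()] object.
#' @param geom A [voxel_geom()] object.
#' @return Signal intensity (arbitrary units), same length as `v`.
#' @export
inflow_signal <- function(v, tissue, seq, geom) {
  .warn_saturation(v, seq, "inflow_signal")
  .inflow_core(v, tissue, seq, geom)
}

#' Flip-ordering signal of the measured slice (concentrated TR)
#'
#' Signal of the inflow-sensitive slice when slice selection runs against
#' the flow, so that spins entering the measured slice come from an
#' unexcited region and carry full magnetization. Verbatim slow-flow
#' form: `Afov*kc*(M0m*exp(-TE/T2m)*(Thk*(1-E1) + v*(TR*E1 - TE)) +
#' static)` with `E1 = exp(-TR/T1m)`; algebraically identical to
#' [inflow_signal()] in the slow-flow regime (asserted in the test
#' suite). Above `v = Thk/TR` the clamped spin-fraction form is used and
#' a warning is raised.
#'
#' @inheritParams inflow_signal
#' @return Signal intensity, same length as `v`.
#' @export
flip_signal <- function(v, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  if (seq$distributed) stop("flip_signal is the concentrated-TR (Case 1) form; use flip_signal_distributed")
  if (any(v < 0)) stop("v must be non-negative")
  .warn_saturation(v, seq, "flip_signal")
  unclamped <- v * seq$TR <= seq$Thk
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  verbatim <- geom$Afov * geom$kc *
    (tissue$M0m * e2m * (seq$Thk * (1 - E1m) + v * (seq$TR * E1m - seq$TE)) +
       .static_term(tissue, seq))
  out <- .inflow_core(v, tissue, seq, geom)
  out[unclamped] <- verbatim[unclamped]
  out
}

#' Flop-ordering signal of the measured slice (concentrated TR)
#'
#' Signal of the same slice when selection runs with the flow: the
#' upstream neighbour slice is excited just before the measured slice, so
#' entering spins are as saturated as resident ones and only a thin slab
#' `v*NS*TE` of recently excited / undetected spins reduces the moving
#' contribution: `Afov*kc*(M0m*exp(-TE/T2m)*(Thk - v*NS*TE)*(1-E1) +
#' static)`. Decreasing in `v`; the slab is clamped at zero thickness.
#'
#' @inheritParams inflow_signal
#' @return Signal intensity, same length as `v`.
#' @export
flop_signal <- function(v, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  if (seq$distributed) stop("flop_signal is the concentrated-TR (Case 1) form; use flop_signal_distributed")
  if (any(v < 0)) stop("v must be non-negative")
  .flop_core(v, tissue, seq, geom)
}

#' Flip minus flop difference signal (concentrated TR)
#'
#' The subtraction image signal for a signed voxel velocity. The static
#' pool cancels exactly; in the slow-flow regime the difference is
#' `sign(v) * Afov*kc*M0m*exp(-TE/T2m)*|v|*((TR - NS*TE)*E1 + (NS-1)*TE)`,
#' an odd, linear function of the signed velocity containing no static
#' parameters. Beyond `|v| = Thk/TR` the difference of the clamped flip
#' and flop forms is returned (the saturation plateau exploited for
#' calibration).
#'
#' @param v_signed Signed velocity (mm/s), vectorized. Positive values
#'   denote flow in the direction that makes the measured slice
#'   inflow-sensitive in the flip ordering.
#' @inheritParams inflow_signal
#' @return Signed signal, same length as `v_signed`.
#' @export
flipflop_difference <- function(v_signed, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  if (seq$distributed) stop("use flipflop_distributed for distributed-TR scheduling")
  a <- abs(v_signed)
  s <- sign(v_signed)
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  lin <- geom$Afov * geom$kc * tissue$M0m * e2m * a *
    ((seq$TR - seq$NS * seq$TE) * E1m + (seq$NS - 1) * seq$TE)
  clamped <- a * seq$TR > seq$Thk
  if (any(clamped)) {
    d <- .inflow_core(a[clamped], tissue, seq, geom) -
      .flop_core(a[clamped], tissue, seq, geom)
    lin[clamped] <- d
  }
  s * lin
}

#' Simplified flip-flop difference (fitting kernel)
#'
#' First-order form of [flipflop_difference()] under `NS*TE << TR`:
#' `Afov*kc*M0m*exp(-TE/T2m) * v * TR * exp(-TR/T1m)`. Exactly linear in
#' the signed velocity; this is the default kernel of the multi-TR
#' velocity fit.
#'
#' @inheritParams flipflop_difference
#' @return Signed signal, same length as `v_signed`.
#' @export
flipflop_simplified <- function(v_signed, tissue, seq, geom) {
  geom$Afov * geom$kc * tissue$M0m * exp(-seq$TE / tissue$T2m) *
    v_signed * seq$TR * exp(-seq$TR / tissue$T1m)
}

# --- Case 2: distributed TR ---------------------------------------------

#' Flip-ordering signal with distributed slice scheduling
#'
#' With slices spread at `TR/NS` intervals the inflow-sensitive slice
#' keeps the same structure as the concentrated case up to terms of order
#' `TE`: `Afov*kc*(M0m*exp(-TE/T2m)*(Thk*(1-E1) + v*TR*E1) + static)`.
#' Assumes `TE << TR/NS` (warned at construction of the sequence).
#'
#' @inheritParams inflow_signal
#' @return Signal intensity, same length as `v`.
#' @export
flip_signal_distributed <- function(v, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  if (!seq$distributed) stop("sequence is not distributed; use flip_signal")
  if (any(v < 0)) stop("v must be non-negative")
  .warn_saturation(v, seq, "flip_signal_distributed")
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  geom$Afov * geom$kc *
    (tissue$M0m * e2m * (seq$Thk * (1 - E1m) + pmin(v * seq$TR, seq$Thk) * E1m) +
       .static_term(tissue, seq))
}

#' Flop-ordering signal with distributed slice scheduling
#'
#' The upstream slice is excited `TR/NS` before the measured one, so a
#' fraction `v*TR/NS / Thk` of spins enters with partial recovery
#' `1 - exp(-TR/(NS*T1m))` while the rest carries `1 - exp(-TR/T1m)`.
#' Two verbatim rearrangements of the same expression are computed and
#' their equality asserted:
#' `v*TR/NS*(1 - e^{-TR/(NS T1m)}) + (Thk - v*TR/NS)*(1 - E1)` and
#' `Thk*(1-E1) + v*TR/NS*(E1 - e^{-TR/(NS T1m)})`.
#'
#' @inheritParams inflow_signal
#' @return Signal intensity, same length as `v`.
#' @export
flop_signal_distributed <- function(v, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  if (!seq$distributed) stop("sequence is not distributed; use flop_signal")
  if (any(v < 0)) stop("v must be non-negative")
  e2m <- exp(-seq$TE / tissue$T2m)
  E1m <- exp(-seq$TR / tissue$T1m)
  ENS <- exp(-seq$TR / (seq$NS * tissue$T1m))
  slab <- pmin(v * seq$TR / seq$NS, seq$Thk)
  form_a <- slab * (1 - ENS) + (seq$Thk - slab) * (1 - E1m)
  form_b <- seq$Thk * (1 - E1m) + slab * (E1m - ENS)
  stopifnot(isTRUE(all.equal(form_a, form_b, tolerance = 1e-12)))
  geom$Afov * geom$kc * (tissue$M0m * e2m * form_a + .static_term(tissue, seq))
}

#' Flip minus flop difference with distributed scheduling
#'
#' `sign(v) * Afov*kc*M0m*exp(-TE/T2m)*|v|*TR*((1 - 1/NS)*e^{-TR/T1m} +
#' (1/NS)*e^{-TR/(NS*T1m)})`. Odd in the signed velocity; for `NS = 1`
#' the kernel formally reduces to the concentrated simplified kernel
#' `TR*e^{-TR/T1m}`.
#'
#' @inheritParams flipflop_difference
#' @return Signed signal, same length as `v_signed`.
#' @export
flipflop_distributed <- function(v_signed, tissue, seq, geom) {
  stopifnot(inherits(seq, "seq_params"))
  E1m <- exp(-seq$TR / tissue$T1m)
  ENS <- exp(-seq$TR / (seq$NS * tissue$T1m))
  geom$Afov * geom$kc * tissue$M0m * exp(-seq$TE / tissue$T2m) *
    v_signed * seq$TR * ((1 - 1 / seq$NS) * E1m + (1 / seq$NS) * ENS)
}
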