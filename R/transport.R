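#' Discrete spin-transport oracle for the slice signal
#'
#' Independent numerical check of the closed-form slice signals: a 1-D
#' column of spin parcels is advected at constant speed `v` along the
#' slice axis; slice-selective excitations saturate the longitudinal
#' magnetization of every parcel they touch, recovery between events is
#' exponential in `T1m`, and readout applies the `exp(-TE/T2m)` echo
#' weighting to parcels that remain inside the measured slice from
#' excitation to echo. Parcels entering the slice between excitation and
#' echo are not detected (they missed the 90-degree pulse) and are
#' treated as saturated afterwards.
#'
#' Orderings: `"flip"` — the measured slice is the only excited region on
#' the flow path, so inflow arrives fully magnetized; `"flop"` — an
#' upstream slab of the same thickness is excited a gap before the
#' measured slice each cycle (`TE` for concentrated scheduling, `TR/NS`
#' for distributed), so inflow arrives freshly saturated.
#'
#' The returned value converges to the matching closed form (flip:
#' [flip_signal()]; flop: [flop_signal()] / [flop_signal_distributed()])
#' as `n_spins` grows, once a steady state is reached. The static-pool
#' contribution is added analytically. Above the slow-flow bound
#' `v > Thk/TR` the flip signal plateaus (inflow fully replaces the
#' slice), which is the saturation regime the closed forms clamp to.
#'
#' @param v Non-negative speed (mm/s), scalar.
#' @param tissue A [tissue_params()] object.
#' @param seq A [seq_params()] object (its `distributed` flag selects the
#'   flop gap).
#' @param ordering `"flip"` or `"flop"`.
#' @param n_spins Number of parcels discretizing the column.
#' @param n_periods Number of TR periods simulated before readout;
#'   default covers both magnetization steady state (about `6*T1m/TR`)
#'   and full transit of the slice.
#' @return Signal intensity (same units and scaling as the closed forms).
#' @export
transport_oracle <- function(v, tissue, seq, ordering = c("flip", "flop"),
                             n_spins = 10000L, n_periods = NULL) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(tissue, "tissue_params"), inherits(seq, "seq_params"),
            length(v) == 1L, v >= 0)
  geom1 <- structure(list(Afov = 1, kc = 1), class = "voxel_geom")

  TR <- seq$TR; TE <- seq$TE; Thk <- seq$Thk
  gap <- if (seq$distributed) TR / seq$NS else TE
  if (is.null(n_periods)) {
    transit <- if (v > 0) ceiling(2 * Thk / (v * TR)) else 0
    n_periods <- ceiling(6 * tissue$T1m / TR) + min(transit, 5000)
  }

  # column extent: measured slice [0, Thk]; upstream slab [-Thk, 0] for flop;
  # enough upstream reservoir that fresh spins reach the slice region
  upstream <- v * TR * (n_periods + 2) + 2 * Thk
  z <- seq.int(0, n_spins - 1) / n_spins * (Thk + upstream) - upstream
  dz <- (Thk + upstream) / n_spins
  z <- z + dz / 2
  Mz <- rep(1, n_spins)  # units of M0m

  recover <- function(Mz, dt) 1 - (1 - Mz) * exp(-dt / tissue$T1m)

  # events within a period, relative times; last event is the measured-slice
  # excitation (readout happens there)
  events <- if (ordering == "flip") {
    list(list(t = 0, a = 0, b = Thk, readout = TRUE))
  } else {
    list(list(t = 0, a = -Thk, b = 0, readout = FALSE),
         list(t = gap, a = 0, b = Thk, readout = TRUE))
  }

  signal_moving <- NA_real_
  for (p in seq_len(n_periods)) {
    t_now <- 0
    for (ev in events) {
      dt <- ev$t - t_now
      if (dt > 0) {
        z <- z + v * dt
        Mz <- recover(Mz, dt)
        t_now <- ev$t
      }
      if (ev$readout && p == n_periods) {
        inside <- z >= ev$a & z <= ev$b - v * TE
        signal_moving <- sum(Mz[inside]) * dz * exp(-TE / tissue$T2m)
      }
      # saturate everything the pulse pair touches during [t, t + TE]
      Mz[z >= ev$a - v * TE & z <= ev$b] <- 0
    }
    dt <- TR - t_now
    z <- z + v * dt
    Mz <- recover(Mz, dt)
  }

  tissue$M0m * signal_moving + .static_term(tissue, seq)
}
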