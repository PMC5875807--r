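#' Poiseuille flow descriptor for a circular tube
#'
#' @param R Tube (lumen) radius, mm.
#' @param vmax Peak (centerline) velocity, mm/s, non-negative.
#' @param sign Flow direction along the slice axis, +1 or -1.
#' @return An object of class `poiseuille_flow`.
#' @export
poiseuille_flow <- function(R, vmax, sign = 1) {
  if (R <= 0) stop("R must be positive")
  if (vmax < 0) stop("vmax must be non-negative")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(R = R, vmax = vmax, sign = sign), class = "poiseuille_flow")
}

#' Laminar radial velocity profile
#'
#' `v(r) = vmax * (1 - (r/R)^2)` for `0 <= r <= R`: the parabolic profile
#' of fully developed laminar flow in a circular tube.
#'
#' @param flow A [poiseuille_flow()] object.
#' @param r Radius (mm), vectorized; must lie in `[0, R]`.
#' @return Unsigned velocity (mm/s).
#' @export
radial_velocity <- function(flow, r) {
  stopifnot(inherits(flow, "poiseuille_flow"))
  if (any(r < 0 | r > flow$R)) stop("r must lie in [0, R]")
  flow$vmax * (1 - (r / flow$R)^2)
}

#' Cross-sectional mean of the Poiseuille profile
#'
#' The area average `(1/(pi R^2)) * integral of v(r) 2 pi r dr` over the
#' disc, which for a parabolic profile is exactly `vmax/2`. Both the
#' closed form and an adaptive quadrature of the defining integral are
#' available; the quadrature serves as an independent oracle in tests.
#'
#' @param flow A [poiseuille_flow()] object.
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return Mean velocity (mm/s), unsigned.
#' @export
mean_velocity <- function(flow, method = c("closed", "quadrature")) {
  stopifnot(inherits(flow, "poiseuille_flow"))
  method <- match.arg(method)
  if (method == "closed") return(flow$vmax / 2)
  if (flow$vmax == 0) return(0)
  q <- stats::integrate(function(r) radial_velocity(flow, r) * 2 * pi * r,
                        0, flow$R, rel.tol = 1e-10, abs.tol = 0)
  q$value / (pi * flow$R^2)
}

#' Saturation (truncation) model of the inflow measurement
#'
#' Above the saturation velocity `vsat = Thk/TR` the inflow replaces the
#' slice completely within one repetition period and the measured
#' apparent velocity clips at `vsat`.
#'
#' @param Thk Slice thickness (mm).
#' @param TR Repetition time (s).
#' @return An object of class `saturation_model` with field `vsat` (mm/s).
#' @export
saturation_model <- function(Thk, TR) {
  if (Thk <= 0 || TR <= 0) stop("Thk and TR must be positive")
  structure(list(Thk = Thk, TR = TR, vsat = Thk / TR), class = "saturation_model")
}

#' Radius of the saturated (clipped) core
#'
#' Solves `Thk/TR = vmax * (1 - (rsat/R)^2)` for `rsat`: the radius
#' inside which `v(r)` exceeds the saturation velocity. Zero when the
#' whole profile is below saturation (`vmax <= vsat`).
#'
#' @param flow A [poiseuille_flow()] object.
#' @param sat A [saturation_model()] object.
#' @return Radius (mm) in `[0, R]`.
#' @export
saturation_radius <- function(flow, sat) {
  stopifnot(inherits(flow, "poiseuille_flow"), inherits(sat, "saturation_model"))
  if (flow$vmax <= sat$vsat) return(0)
  flow$R * sqrt(1 - sat$vsat / flow$vmax)
}

#' Mean of the truncated (saturation-clipped) Poiseuille profile
#'
#' Area average of `min(v(r), vsat)` over the disc when the core is
#' clipped at the saturation velocity. Closed form:
#' `vsat * (1 - vsat/(2*vmax))` with `vsat = Thk/TR`; the direct
#' quadrature of the clipped integrand is available as an oracle.
#' Continuous with [mean_velocity()] at `vmax = vsat` (both give
#' `vmax/2`).
#'
#' @inheritParams saturation_radius
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return Mean apparent velocity (mm/s).
#' @export
truncated_mean_velocity <- function(flow, sat, method = c("closed", "quadrature")) {
  stopifnot(inherits(flow, "poiseuille_flow"), inherits(sat, "saturation_model"))
  method <- match.arg(method)
  if (flow$vmax == 0) return(0)
  if (method == "closed")
    return(sat$vsat * (1 - 0.5 * sat$vsat / flow$vmax))
  q <- stats::integrate(function(r) pmin(radial_velocity(flow, r), sat$vsat) * 2 * pi * r,
                        0, flow$R, rel.tol = 1e-10, abs.tol = 0)
  q$value / (pi * flow$R^2)
}

#' Apparent mean velocity across both regimes
#'
#' Piecewise (Heaviside-selected) mean of the apparent velocity map:
#' `vmax/2` while `TR <= Thk/vmax` (untruncated; the boundary is assigned
#' to this branch) and the truncated mean `vsat*(1 - vsat/(2*vmax))`
#' beyond. Continuous at the regime boundary; non-increasing in `TR`
#' past it. Vectorized over `vmax` and `TR`.
#'
#' @param vmax Peak velocity (mm/s), vectorized.
#' @param Thk Slice thickness (mm).
#' @param TR Repetition time (s), vectorized.
#' @return Mean apparent velocity (mm/s).
#' @export
apparent_mean_velocity <- function(vmax, Thk, TR) {
  if (Thk <= 0 || any(TR <= 0)) stop("Thk and TR must be positive")
  if (any(vmax < 0)) stop("vmax must be non-negative")
  n <- max(length(vmax), length(TR))
  vmax <- rep_len(vmax, n)
  vsat <- rep_len(Thk / TR, n)
  out <- vmax / 2
  trunc <- vmax > vsat  # strict: boundary stays on the untruncated branch
  out[trunc] <- vsat[trunc] * (1 - 0.5 * vsat[trunc] / vmax[trunc])
  out
}
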