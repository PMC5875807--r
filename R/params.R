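#' Tissue relaxation and magnetization parameters
#'
#' Bundles the equilibrium magnetizations and relaxation times of the two
#' spin pools in a voxel: the moving pool (flowing liquid, subscript `m`)
#' and the static pool (immobile tissue or background, subscript `s`).
#'
#' @param M0m Equilibrium magnetization of the moving spins (arbitrary
#'   signal units).
#' @param M0s Equilibrium magnetization of the static spins (same units).
#' @param T1m,T1s Longitudinal relaxation times of moving and static
#'   spins (s).
#' @param T2m,T2s Transverse relaxation times of moving and static spins
#'   (s).
#' @return An object of class `tissue_params`.
#' @details All values must be strictly positive. `T2 > T1` for either
#'   pool is physically implausible and triggers a warning (not an
#'   error), since fitted or literature values occasionally violate it
#'   marginally.
#' @examples
#' water <- tissue_params(M0m = 1, M0s = 0, T1m = 2.46, T1s = 1,
#'                        T2m = 2, T2s = 0.05)
#' @export
tissue_params <- function(M0m, M0s, T1m, T1s, T2m, T2s) {
  vals <- c(M0m = M0m, M0s = M0s, T1m = T1m, T1s = T1s, T2m = T2m, T2s = T2s)
  if (any(!is.finite(vals)) || any(vals[c("T1m", "T1s", "T2m", "T2s")] <= 0))
    stop("relaxation times must be finite and strictly positive")
  if (M0m < 0 || M0s < 0)
    stop("equilibrium magnetizations must be non-negative")
  if (T2m > T1m || T2s > T1s)
    warning("T2 exceeds T1 for at least one pool; physically implausible")
  structure(as.list(vals), class = "tissue_params")
}

#' Acquisition timing and geometry of a multi-slice spin-echo sequence
#'
#' @param TR Repetition time (s): interval between successive excitations
#'   of the same slice.
#' @param TE Echo time (s).
#' @param Thk Slice thickness (mm).
#' @param NS Number of slices (integer, >= 2 for the flip/flop scheme;
#'   `NS = 1` is admitted for formal limit checks).
#' @param FOV_read,FOV_phase Field of view along read and phase axes (mm).
#' @param N_read,N_phase Matrix size along read and phase axes.
#' @param distributed If `FALSE` (default) slice acquisitions are
#'   consecutive within each TR ("concentrated" scheduling, Case 1); if
#'   `TRUE` they are spread evenly at intervals `TR/NS` (Case 2).
#' @param AVG Number of averaged acquisitions (integer >= 1).
#' @param te_ratio_max For distributed scheduling the signal expressions
#'   assume `TE` much smaller than `TR/NS`; a warning is issued when
#'   `TE >= TR/(te_ratio_max * NS)`. Default 4.
#' @return An object of class `seq_params`.
#' @examples
#' seq_params(TR = 1.2, TE = 0.015, Thk = 0.5, NS = 2,
#'            FOV_read = 20, FOV_phase = 20, N_read = 128, N_phase = 128)
#' @export
seq_params <- function(TR, TE, Thk, NS = 2L,
                       FOV_read = 20, FOV_phase = 20,
                       N_read = 128L, N_phase = 128L,
                       distributed = FALSE, AVG = 1L,
                       te_ratio_max = 4) {
  if (TR <= 0 || TE <= 0 || Thk <= 0) stop("TR, TE and Thk must be positive")
  if (TE >= TR) stop("TE must be smaller than TR")
  NS <- as.integer(NS); AVG <- as.integer(AVG)
  if (NS < 1L) stop("NS must be a positive integer")
  if (AVG < 1L) stop("AVG must be >= 1")
  if (FOV_read <= 0 || FOV_phase <= 0 || N_read < 1 || N_phase < 1)
    stop("FOV and matrix dimensions must be positive")
  if (!distributed && NS * TE >= TR)
    stop("concentrated scheduling requires NS*TE < TR")
  if (distributed && TE >= TR / (te_ratio_max * NS))
    warning(sprintf("distributed scheduling assumes TE << TR/NS; TE = %g >= TR/(%g*NS)",
                    TE, te_ratio_max))
  structure(list(TR = TR, TE = TE, Thk = Thk, NS = NS,
                 FOV_read = FOV_read, FOV_phase = FOV_phase,
                 N_read = as.integer(N_read), N_phase = as.integer(N_phase),
                 distributed = isTRUE(distributed), AVG = AVG),
            class = "seq_params")
}

#' In-plane voxel geometry and coil scale
#'
#' @param seq A [seq_params()] object; the in-plane voxel area is
#'   `Afov = FOV_read*FOV_phase/(N_read*N_phase)` (mm^2).
#' @param kc Coil sensitivity coefficient, a dimensionless overall signal
#'   scale (default 1).
#' @return An object of class `voxel_geom` with fields `Afov` and `kc`.
#' @export
voxel_geom <- function(seq, kc = 1) {
  stopifnot(inherits(seq, "seq_params"))
  if (kc <= 0) stop("kc must be positive")
  Afov <- seq$FOV_read * seq$FOV_phase / (seq$N_read * seq$N_phase)
  structure(list(Afov = Afov, kc = kc), class = "voxel_geom")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (moving | static pool)\n")
  cat(sprintf("  M0: %.4g | %.4g   T1 (s): %.4g | %.4g   T2 (s): %.4g | %.4g\n",
              x$M0m, x$M0s, x$T1m, x$T1s, x$T2m, x$T2s))
  invisible(x)
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf("SEMS sequence: TR = %g s, TE = %g s, Thk = %g mm, NS = %d, AVG = %d\n",
              x$TR, x$TE, x$Thk, x$NS, x$AVG))
  cat(sprintf("  FOV %g x %g mm, matrix %d x %d, scheduling: %s\n",
              x$FOV_read, x$FOV_phase, x$N_read, x$N_phase,
              if (x$distributed) "distributed (TR/NS spacing)" else "concentrated"))
  invisible(x)
}

#' Serialize acquisition/tissue parameters to JSON
#'
#' `params_to_json()` and `params_from_json()` round-trip
#' [tissue_params()] and [seq_params()] records through JSON strings or
#' files, for use in sidecar metadata and run configurations.
#'
#' @param x A `tissue_params` or `seq_params` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return `params_to_json()` returns the JSON string invisibly when
#'   `path` is given, visibly otherwise. `params_from_json()` returns the
#'   reconstructed object.
#' @export
params_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, c("tissue_params", "seq_params")))
  rec <- c(list(.class = class(x)[1]), unclass(x))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @param json A JSON string, or a file path when `file = TRUE`.
#' @param file Whether `json` names a file.
#' @rdname params_to_json
#' @export
params_from_json <- function(json, file = FALSE) {
  rec <- jsonlite::fromJSON(if (file) paste(readLines(json), collapse = "\n") else json)
  cls <- rec$.class
  rec$.class <- NULL
  switch(cls,
         tissue_params = do.call(tissue_params, rec),
         seq_params = do.call(seq_params, rec),
         stop("unknown record class in JSON: ", cls))
}

# internal: update TR of a seq_params, revalidating
set_tr <- function(seq, TR) {
  args <- unclass(seq)
  args$TR <- TR
  do.call(seq_params, args)
}
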