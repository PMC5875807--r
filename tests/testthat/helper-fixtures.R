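# shared fixtures: water-like moving pool, weak static background,
# 2-slice concentrated sequence at the bench geometry
fx_tissue <- function(M0s = 0.3, T1s = 1, T2s = 0.05) {
  tissue_params(M0m = 1, M0s = M0s, T1m = 2.46, T1s = T1s, T2m = 2, T2s = T2s)
}

fx_seq <- function(TR = 1.2, TE = 0.015, Thk = 0.5, NS = 2L, ...) {
  seq_params(TR = TR, TE = TE, Thk = Thk, NS = NS,
             FOV_read = 20, FOV_phase = 20, N_read = 128L, N_phase = 128L, ...)
}

fx_geom <- function(seq = fx_seq(), kc = 1) voxel_geom(seq, kc)

# random parameter draw for property-style loops
fx_draw <- function() {
  T1m <- runif(1, 0.5, 4)
  T1s <- runif(1, 0.2, 2)
  list(tissue = tissue_params(M0m = runif(1, 0.5, 2), M0s = runif(1, 0, 1),
                              T1m = T1m, T1s = T1s,
                              T2m = T1m * runif(1, 0.2, 1),
                              T2s = T1s * runif(1, 0.05, 0.5)),
       seq = seq_params(TR = runif(1, 0.5, 3), TE = runif(1, 0.005, 0.03),
                        Thk = runif(1, 0.3, 1.5), NS = sample(2:4, 1)))
}
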