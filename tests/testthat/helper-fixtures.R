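# Shared fixtures: preset band models and calibration matrices built in code.

preset_fixture <- function() {
  pre <- study_presets()
  stds <- align_to_grid(list(
    component_spectrum(pre$hct, 5, pre$grid, "HCT5"),
    component_spectrum(pre$lsp, 20, pre$grid, "LSP20")))
  pre$H <- build_sensitivity_matrix(stds, c(HCT = 5, LSP = 20))
  pre
}

# small exactly-solvable system: H c = A with c = (2, 3)
tiny_system <- function() {
  H <- kf_sensitivity(grid = c(240, 250, 260), components = c("a", "b"),
                      values = matrix(c(1, 0.2, 0.3, 0.5, 1, 0.8), ncol = 2))
  A <- drop(H$values %*% c(2, 3))
  list(H = H, sample = kf_spectrum(c(240, 250, 260), A, "exact"),
       truth = c(2, 3))
}

# randomized full-rank sensitivity matrix + noiseless sample
random_system <- function(n_comp, n_wl) {
  vals <- matrix(stats::runif(n_wl * n_comp, 0.01, 1), n_wl, n_comp)
  H <- kf_sensitivity(seq(220, by = 1, length.out = n_wl),
                      paste0("c", seq_len(n_comp)), vals)
  truth <- stats::runif(n_comp, 0.5, 20)
  sample <- kf_spectrum(H$grid, drop(vals %*% truth), "rand")
  list(H = H, sample = sample, truth = truth)
}
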