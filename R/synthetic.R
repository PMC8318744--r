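#' Gaussian band model of a pure-component spectrum
#'
#' Parameterizes a component's unit-concentration absorptivity as a sum of
#' Gaussian bands. Real drug spectra are not Gaussian, but a few bands
#' reproduce the essential feature the unmixing problem turns on: strongly
#' overlapping absorption envelopes.
#'
#' @param name Component label.
#' @param centers Band centers (nm).
#' @param sigmas Band widths (Gaussian sigma, nm), > 0.
#' @param peaks Peak absorptivities (AU per ug/mL), > 0.
#' @return A `kf_band_model`.
#' @export
band_model <- function(name, centers, sigmas, peaks) {
  stopifnot(length(centers) >= 1,
            length(sigmas) == length(centers),
            length(peaks) == length(centers))
  if (any(sigmas <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(peaks <= 0)) stop("peak absorptivities must be > 0", call. = FALSE)
  structure(list(name = as.character(name)[1],
                 bands = data.frame(center = centers, sigma = sigmas,
                                    peak = peaks)),
            class = "kf_band_model")
}

#' Evaluate a band model at unit concentration
#' @param model A `kf_band_model`.
#' @param grid Wavelengths (nm).
#' @return Numeric vector of unit absorptivities (AU per ug/mL).
#' @export
unit_absorptivity <- function(model, grid) {
  stopifnot(inherits(model, "kf_band_model"))
  if (length(grid) == 0) stop("empty wavelength grid", call. = FALSE)
  b <- model$bands
  out <- numeric(length(grid))
  for (j in seq_len(nrow(b)))
    out <- out + b$peak[j] * exp(-(grid - b$center[j])^2 / (2 * b$sigma[j]^2))
  out
}

#' Noiseless Beer-Lambert spectrum of one component
#'
#' `A(lambda) = C * sum_j p_j * exp(-(lambda - mu_j)^2 / (2 sigma_j^2))`.
#'
#' @param model A `kf_band_model`.
#' @param C Concentration (ug/mL), >= 0.
#' @param grid Wavelengths (nm), non-empty.
#' @param label Spectrum label (default `"<name><C>"`).
#' @return A `kf_spectrum`.
#' @export
component_spectrum <- function(model, C, grid,
                               label = sprintf("%s%g", model$name, C)) {
  if (length(grid) == 0) stop("empty wavelength grid", call. = FALSE)
  if (!is.finite(C) || C < 0) stop("concentration must be >= 0", call. = FALSE)
  kf_spectrum(grid, C * unit_absorptivity(model, grid), label)
}

#' Simulate replicate mixture spectra with additive noise
#'
#' Sums the noiseless component spectra (Beer-Lambert additivity) and adds
#' i.i.d. Gaussian absorbance noise of SD `sigma`. Replicates are drawn as
#' consecutive substreams of one seeded generator, so a fixed seed makes
#' the whole set reproducible.
#'
#' @param models List of `kf_band_model`, one per component.
#' @param concentrations Numeric vector of concentrations (ug/mL), one per
#'   model, >= 0.
#' @param grid Wavelengths (nm).
#' @param replicates Number of replicate spectra (default 1).
#' @param sigma Additive absorbance noise SD (AU), >= 0 (default 0.002).
#' @param seed Optional integer seed.
#' @param label_prefix Prefix for replicate labels.
#' @return A `kf_spectrum_set` of `replicates` spectra.
#' @export
mixture_spectrum <- function(models, concentrations, grid, replicates = 1,
                             sigma = 0.002, seed = NULL,
                             label_prefix = "mixture") {
  if (length(models) != length(concentrations))
    stop("need one band model per designed component", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  clean <- numeric(length(grid))
  for (i in seq_along(models))
    clean <- clean + concentrations[i] * unit_absorptivity(models[[i]], grid)
  sp <- lapply(seq_len(replicates), function(k) {
    noise <- if (sigma > 0) stats::rnorm(length(grid), 0, sigma) else 0
    kf_spectrum(grid, clean + noise, sprintf("%s_r%d", label_prefix, k))
  })
  align_to_grid(sp)
}

#' Built-in two-drug study presets
#'
#' Band models emulating the hydrochlorothiazide-like and losartan-like
#' pair: strongly overlapping UV envelopes with absorbance maxima near
#' 272 nm (HCT) and 235 nm (LSP), on the 220-300 nm grid at 1 nm steps.
#' Peak absorptivities are fixture constants scaled so the customary 5 and
#' 20 ug/mL standards peak in a plausible 0.2-0.8 AU range; they are not
#' measured values.
#'
#' @return List with elements `hct` and `lsp` (band models) and `grid`.
#' @export
study_presets <- function() {
  list(
    hct = band_model("HCT", centers = c(225, 272), sigmas = c(6, 9),
                     peaks = c(0.030, 0.070)),
    lsp = band_model("LSP", centers = c(235, 262), sigmas = c(13, 12),
                     peaks = c(0.0220, 0.004)),
    grid = seq(220, 300, by = 1)
  )
}

#' Standard-mixture study designs
#'
#' The seven two-component accuracy/repeatability designs: HCT from 1 to
#' 6 ug/mL against LSP from 24 down to 4, plus the tablet-like 5 + 20
#' combination.
#'
#' @return Data frame with columns `design`, `hct`, `lsp` (ug/mL).
#' @export
study_designs <- function() {
  data.frame(design = paste0("M", 1:7),
             hct = c(1, 2, 3, 4, 5, 6, 5),
             lsp = c(24, 20, 16, 12, 8, 4, 20))
}

#' Generate a complete synthetic study fixture on disk
#'
#' Writes CSV spectra for a full validation study: the two single-component
#' standards (HCT 5, LSP 20 ug/mL, noiseless), the seven standard-mixture
#' designs in triplicate, three tablet-like samples (5 + 20 ug/mL), and the
#' spike-recovery set (unspiked base 3 + 12 ug/mL, i.e. three fifths of a
#' tablet weight, plus three spike levels in triplicate: HCT +0.5/+1.0/+1.5,
#' LSP +2/+4/+6 ug/mL). A `manifest.csv` maps each file to its role and
#' true concentrations. Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param sigma Additive absorbance noise SD (AU), default 0.002.
#' @return Path to the manifest, invisibly.
#' @export
generate_study_fixture <- function(dir, seed = 1, sigma = 0.002) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pre <- study_presets()
  grid <- pre$grid
  models <- list(pre$hct, pre$lsp)
  set.seed(seed)

  rows <- list()
  emit <- function(spec, file, role, design, rep, hct, lsp) {
    write_spectrum(spec, file.path(dir, file))
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, role = role, design = design, replicate = rep,
      true_hct = hct, true_lsp = lsp)
  }
  noisy <- function(hct, lsp, label) {
    clean <- hct * unit_absorptivity(pre$hct, grid) +
      lsp * unit_absorptivity(pre$lsp, grid)
    kf_spectrum(grid, clean + stats::rnorm(length(grid), 0, sigma), label)
  }

  # standards: noiseless single-point calibration spectra
  emit(component_spectrum(pre$hct, 5, grid, "HCT5"), "standard_hct5.csv",
       "standard", "HCT", 1, 5, 0)
  emit(component_spectrum(pre$lsp, 20, grid, "LSP20"), "standard_lsp20.csv",
       "standard", "LSP", 1, 0, 20)

  des <- study_designs()
  for (d in seq_len(nrow(des))) for (k in 1:3) {
    f <- sprintf("mixture_%s_r%d.csv", des$design[d], k)
    emit(noisy(des$hct[d], des$lsp[d], sprintf("%s_r%d", des$design[d], k)),
         f, "mixture", des$design[d], k, des$hct[d], des$lsp[d])
  }
  for (k in 1:3)
    emit(noisy(5, 20, sprintf("SP%d", k)), sprintf("tablet_SP%d.csv", k),
         "tablet", "SP", k, 5, 20)
  # spike-recovery: unspiked base then three levels, triplicate each
  base_hct <- 3; base_lsp <- 12
  spikes <- data.frame(level = 0:3, hct = c(0, 0.5, 1.0, 1.5),
                       lsp = c(0, 2, 4, 6))
  for (s in seq_len(nrow(spikes))) for (k in 1:3) {
    f <- sprintf("spike_S%d_r%d.csv", spikes$level[s], k)
    emit(noisy(base_hct + spikes$hct[s], base_lsp + spikes$lsp[s],
               sprintf("S%d_r%d", spikes$level[s], k)),
         f, if (spikes$level[s] == 0) "unspiked" else "spiked",
         sprintf("S%d", spikes$level[s]), k,
         base_hct + spikes$hct[s], base_lsp + spikes$lsp[s])
  }

  manifest <- do.call(rbind, rows)
  manifest$spike_hct <- 0; manifest$spike_lsp <- 0
  sp_ix <- manifest$role == "spiked"
  lev <- as.integer(sub("S", "", manifest$design[sp_ix]))
  manifest$spike_hct[sp_ix] <- spikes$hct[lev + 1]
  manifest$spike_lsp[sp_ix] <- spikes$lsp[lev + 1]
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
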