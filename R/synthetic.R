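#' Configuration of the synthetic burn-spectra generator
#'
#' Parameterizes a seeded simulator of labeled visible/near-infrared
#' reflectance curves with the qualitative structure of contact-burn skin
#' spectra: six temperature classes (50-300 \eqn{^\circ}C), a smooth baseline
#' rising into the NIR, a class-dependent absorption dip around 670 nm whose
#' depth *decreases* with burn temperature (absorption components such as
#' keratin are progressively lost in burned tissue, so hotter burns absorb
#' less in the 600-700 nm window), class-dependent NIR bumps standing in for
#' sum-frequency / second-harmonic organic absorptions, a per-curve
#' multiplicative illumination scalar, and per-band additive Gaussian noise.
#'
#' The defaults are the package's study conditions: 260 bands over
#' 400-1000 nm, six classes, a linear dip-depth schedule from 0.30 (50
#' \eqn{^\circ}C) down to 0.05 (300 \eqn{^\circ}C), illumination sd 0.10 and
#' additive noise sd 0.05. Adjacent temperature classes have the most similar
#' templates by construction, so 150 vs 200 \eqn{^\circ}C is the hardest pair.
#'
#' @param n_bands Number of spectral bands (default 260).
#' @param wavelength_range Numeric length-2, nm (default `c(400, 1000)`).
#' @param n_classes Number of classes (default 6).
#' @param class_labels Character class names (default `"50 °C" ... "300 °C"`).
#' @param samples_per_class Spectra generated per class (default 1000).
#' @param dip_center Center of the visible absorption dip, nm (default 670).
#' @param dip_width Gaussian sd of the dip, nm (default 30; the dip lives in
#'   the 600-700 nm window).
#' @param dip_depth_by_class Length-`n_classes` decreasing vector of dip
#'   depths in `[0, 1]`.
#' @param nir_center,nir_width Center/sd of the NIR feature, nm.
#' @param nir_amp_by_class Length-`n_classes` amplitudes of the NIR bump.
#' @param illum_scale_sd Sd of the per-curve multiplicative illumination
#'   factor `(1 + s)`.
#' @param noise_sd Sd of the per-band additive Gaussian noise.
#' @param seed Integer generator seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bands = 260,
                             wavelength_range = c(400, 1000),
                             n_classes = 6,
                             class_labels = paste0(seq(50, by = 50,
                                                       length.out = n_classes),
                                                   " °C"),
                             samples_per_class = 1000,
                             dip_center = 670,
                             dip_width = 30,
                             dip_depth_by_class = seq(0.30, 0.05,
                                                      length.out = n_classes),
                             nir_center = 930,
                             nir_width = 45,
                             nir_amp_by_class = seq(0.02, 0.12,
                                                    length.out = n_classes),
                             illum_scale_sd = 0.10,
                             noise_sd = 0.05,
                             seed = 0) {
  stopifnot(n_bands >= 2, n_classes >= 2, samples_per_class >= 1,
            length(dip_depth_by_class) == n_classes,
            length(nir_amp_by_class) == n_classes)
  if (illum_scale_sd < 0 || noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (any(diff(dip_depth_by_class) > 0)) {
    stop("dip_depth_by_class must be non-increasing with temperature",
         call. = FALSE)
  }
  structure(list(
    n_bands = as.integer(n_bands),
    wavelength_range = wavelength_range,
    n_classes = as.integer(n_classes),
    class_labels = class_labels,
    samples_per_class = as.integer(samples_per_class),
    dip_center = dip_center, dip_width = dip_width,
    dip_depth_by_class = dip_depth_by_class,
    nir_center = nir_center, nir_width = nir_width,
    nir_amp_by_class = nir_amp_by_class,
    illum_scale_sd = illum_scale_sd, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Wavelength grid of a synthetic configuration
#' @param cfg A [synthetic_config].
#' @return Numeric vector of length `n_bands`, strictly increasing, nm.
#' @export
synthetic_wavelengths <- function(cfg) {
  seq(cfg$wavelength_range[1], cfg$wavelength_range[2],
      length.out = cfg$n_bands)
}

#' Class-conditional reflectance template
#'
#' The deterministic mean curve of one class: a smooth sigmoidal baseline
#' rising from the blue into the NIR (loosely imitating skin reflectance),
#' minus a Gaussian absorption dip at `dip_center` with the class's depth,
#' plus the class's Gaussian NIR bump. Deterministic given the configuration.
#'
#' @param cfg A [synthetic_config].
#' @param class_index 0-based class index in `[0, n_classes)`.
#' @return Numeric vector of length `n_bands`.
#' @export
#' @examples
#' cfg <- synthetic_config()
#' plot(synthetic_wavelengths(cfg), class_template(cfg, 0), type = "l")
class_template <- function(cfg, class_index) {
  stopifnot(inherits(cfg, "synthetic_config"))
  k <- as.integer(class_index)
  if (k < 0L || k >= cfg$n_classes) {
    stop(sprintf("class_index must lie in [0, %d)", cfg$n_classes),
         call. = FALSE)
  }
  wl <- synthetic_wavelengths(cfg)
  # smooth baseline: rises through the visible, flattens in the NIR; overall
  # level drifts slightly with charring (hotter burns darken the tissue)
  level <- 0.55 - 0.03 * k / (cfg$n_classes - 1)
  base <- level / (1 + exp(-(wl - 600) / 80)) + 0.12
  dip <- cfg$dip_depth_by_class[k + 1] *
    exp(-0.5 * ((wl - cfg$dip_center) / cfg$dip_width)^2)
  nir <- cfg$nir_amp_by_class[k + 1] *
    exp(-0.5 * ((wl - cfg$nir_center) / cfg$nir_width)^2)
  pmin(pmax(base - dip + nir, 0), 1.2)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `samples_per_class` spectra per class: the class template scaled by
#' a per-curve illumination factor `1 + s`, `s ~ N(0, illum_scale_sd)`, plus
#' i.i.d. per-band Gaussian noise of sd `noise_sd`, clipped to `[0, 1.2]`.
#' Fully seeded: the same configuration always yields a bit-identical
#' dataset, and the noise draws do not depend on `samples_per_class` of other
#' classes.
#'
#' @param cfg A [synthetic_config].
#' @return A [spectral_dataset] with `n_classes * samples_per_class` spectra.
#' @export
#' @examples
#' ds <- generate_spectra(synthetic_config(samples_per_class = 5))
#' ds
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  D <- cfg$n_bands
  n <- cfg$samples_per_class
  blocks <- vector("list", cfg$n_classes)
  for (k in seq_len(cfg$n_classes) - 1L) {
    tmpl <- class_template(cfg, k)
    set.seed(subseed(cfg$seed, paste0("class", k)))
    illum <- 1 + rnorm(n, 0, cfg$illum_scale_sd)
    noise <- matrix(rnorm(n * D, 0, cfg$noise_sd), n, D)
    blocks[[k + 1]] <- pmin(pmax(illum %o% tmpl + noise, 0), 1.2)
  }
  spectral_dataset(
    do.call(rbind, blocks),
    labels = rep(seq_len(cfg$n_classes) - 1L, each = n),
    wavelengths = synthetic_wavelengths(cfg),
    class_names = cfg$class_labels,
    provenance = sprintf("synthetic(seed=%d, noise_sd=%g, illum_sd=%g)",
                         cfg$seed, cfg$noise_sd, cfg$illum_scale_sd)
  )
}

#' Datasets at increasing noise levels
#'
#' Regenerates the dataset at each additive-noise level, holding the
#' templates, the illumination draws and the noise *directions* fixed (the
#' same seed schedule is used for every level), so level 0 reproduces
#' `generate_spectra(cfg)` exactly and the only change across levels is the
#' noise magnitude.
#'
#' @param cfg A [synthetic_config] (its `noise_sd` is ignored).
#' @param noise_levels Non-negative, increasing numeric vector of noise sds.
#' @return A list of [spectral_dataset]s, one per level.
#' @export
difficulty_sweep <- function(cfg, noise_levels) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (any(noise_levels < 0)) {
    stop("noise levels must be non-negative", call. = FALSE)
  }
  if (is.unsorted(noise_levels, strictly = FALSE)) {
    stop("noise levels must be increasing", call. = FALSE)
  }
  lapply(noise_levels, function(s) {
    c2 <- cfg
    c2$noise_sd <- s
    generate_spectra(c2)
  })
}
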