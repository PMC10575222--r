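#' Generative specification for a synthetic two-season seed dataset
#'
#' Builds the parameter set for the synthetic stand-in dataset: per-variety
#' mean reflectance spectra (smooth Gaussian-bump curves over the band axis,
#' scaled into \[0.1, 0.9\]), a systematic affine per-band spectral drift
#' (additive offset plus multiplicative gain) applied to the target season,
#' an elliptical seed silhouette inside a fixed frame, seed-level spectral
#' jitter and pixel-level noise. All drift components scale linearly with
#' `shift_magnitude`; at 0 the two seasons are identically distributed.
#'
#' The default drift is a global affine transform shared by all varieties.
#' Because seasonal change in real panels arises from genotype-by-environment
#' interaction, an optional class-coupled additive component that displaces
#' each variety's spectrum differently can be switched on with
#' `class_shift > 0` (off by default).
#'
#' Two realism flags mimic structure seen in real multi-variety panels:
#' `hard_pair` gives the first two classes nearly coincident spectral bumps
#' (closely related varieties that are easily confused), and `outlier_class`
#' gives the last class extra spectral separation (one variety that is
#' consistently easiest to recognise).
#'
#' @param n_classes number of varieties (>= 2), default 4.
#' @param n_bands number of spectral bands (>= 2), default 94.
#' @param shift_magnitude nonnegative scale of the season-to-season drift.
#'   The default 0.3 is calibrated so that a source-only CNN collapses on the
#'   target season the way single-season models do on a new harvest year.
#' @param spatial_shape frame `(rows, cols)` the seed ellipse is drawn in.
#' @param pixel_noise_sd per-pixel, per-band Gaussian noise (reflectance).
#' @param within_class_sd seed-level spectral jitter (reflectance): each seed
#'   draws a random baseline offset, a random spectral tilt and two random
#'   localized bumps of this scale, mimicking the biological seed-to-seed
#'   variability that makes small labeled samples unrepresentative.
#' @param hard_pair,outlier_class realism flags, see Details.
#' @param class_shift relative strength of the optional class-coupled drift
#'   component (0 disables it, the default; 0.5 makes each variety's extra
#'   displacement half the global drift amplitude). Useful for sensitivity
#'   analyses of methods that align only the marginal feature distribution.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the spec, including this seed.
#' @return An object of class `synthetic_spec` with the class spectra and
#'   drift vectors materialised.
#' @export
synthetic_spec <- function(n_classes = 4L, n_bands = 94L, shift_magnitude = 0.3,
                           spatial_shape = c(12L, 16L), pixel_noise_sd = 0.05,
                           within_class_sd = 0.08, hard_pair = TRUE,
                           outlier_class = TRUE, class_shift = 0, seed = 1L) {
  if (n_classes < 2L) abort("`n_classes` must be at least 2.")
  if (n_bands < 2L) abort("`n_bands` must be at least 2.")
  if (shift_magnitude < 0 || pixel_noise_sd < 0 || within_class_sd < 0) {
    abort("Magnitudes and standard deviations must be nonnegative.")
  }
  x <- seq(0, 1, length.out = n_bands)
  bump <- function(mu, a, s = 0.08) a * exp(-(x - mu)^2 / (2 * s^2))
  base <- 0.35 + 0.15 * sin(2 * pi * x)
  centers <- seq(0.15, 0.85, length.out = n_classes)
  amps <- rep(0.22, n_classes)
  spectra <- matrix(0, n_classes, n_bands)
  for (c in seq_len(n_classes)) spectra[c, ] <- base + bump(centers[c], amps[c])
  if (isTRUE(hard_pair) && n_classes >= 2L) {
    # classes 1 and 2 share almost the same bump position; amplitude alone
    # separates them (genetically close varieties)
    spectra[2, ] <- base + bump(centers[1] + 0.05, 0.17)
  }
  if (isTRUE(outlier_class)) {
    # last class: raised baseline + a second bump, well apart from the rest
    spectra[n_classes, ] <- base + 0.06 +
      bump(centers[n_classes], 0.30) + bump(0.05, 0.15)
  }
  rng <- range(spectra)
  spectra <- 0.1 + 0.8 * (spectra - rng[1]) / (rng[2] - rng[1])
  # smooth drift shapes; fixed so the drift scales linearly with magnitude
  offset <- shift_magnitude * 0.5 * sin(2 * pi * x + 0.7)
  gain <- 1 + shift_magnitude * 0.5 * cos(2 * pi * x - 0.4)
  # genotype-by-environment interaction: each variety drifts differently
  class_offset <- matrix(0, n_classes, n_bands)
  for (c in seq_len(n_classes)) {
    class_offset[c, ] <- shift_magnitude * class_shift * 0.5 *
      sin(2 * pi * x + 1.9 + 2 * pi * (c - 1) / n_classes)
  }
  structure(
    list(n_classes = as.integer(n_classes), n_bands = as.integer(n_bands),
         class_spectra = spectra, domain_offset = offset, domain_gain = gain,
         class_offset = class_offset, class_shift = class_shift,
         shift_magnitude = shift_magnitude,
         spatial_shape = as.integer(spatial_shape),
         pixel_noise_sd = pixel_noise_sd, within_class_sd = within_class_sd,
         hard_pair = isTRUE(hard_pair), outlier_class = isTRUE(outlier_class),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec: %d classes x %d bands, frame %d x %d, ",
                     "shift=%.2f, noise=%.3f, jitter=%.3f, seed=%d>\n"),
              x$n_classes, x$n_bands, x$spatial_shape[1], x$spatial_shape[2],
              x$shift_magnitude, x$pixel_noise_sd, x$within_class_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic two-season seed cube dataset
#'
#' Draws `n_per_class_per_domain` seeds for every (variety, season)
#' combination. Each seed is an ellipse of randomly varying axes centred
#' (with +/-1 px jitter) in the frame; pixels inside the ellipse carry the
#' variety's mean spectrum plus a seed-level random baseline/tilt and i.i.d.
#' pixel noise; target-season seeds are then passed through the affine
#' per-band drift `gain * x + offset`. All pixels outside the ellipse are
#' exactly zero. The result is bit-deterministic given the spec (including
#' its seed) and exactly class-balanced.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class_per_domain seeds per variety per season (>= 1).
#' @return A [cube_set()] with `2 * n_classes * n` cubes at the spec's frame
#'   size, class names `class_0 ...`.
#' @export
generate_dataset <- function(spec, n_per_class_per_domain) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(n_per_class_per_domain)
  if (n < 1L) abort("`n_per_class_per_domain` must be >= 1.")
  H <- spec$spatial_shape[1]; W <- spec$spatial_shape[2]; B <- spec$n_bands
  x <- seq(0, 1, length.out = B)
  tilt <- x - 0.5
  cubes <- with_seed(spec$seed, {
    out <- vector("list", 2L * spec$n_classes * n)
    k <- 0L
    for (dom in c("source", "target")) {
      for (cls in seq_len(spec$n_classes)) {
        for (i in seq_len(n)) {
          # ellipse support: semi-axes 25-42% of frame, centre jitter 1 px
          ar <- runif(1, 0.25, 0.42) * H
          ac <- runif(1, 0.25, 0.42) * W
          cy <- (H + 1) / 2 + runif(1, -1, 1)
          cx <- (W + 1) / 2 + runif(1, -1, 1)
          yy <- matrix(seq_len(H), H, W)
          xx <- matrix(seq_len(W), H, W, byrow = TRUE)
          mask <- ((yy - cy) / ar)^2 + ((xx - cx) / ac)^2 <= 1
          npix <- sum(mask)
          # seed-level deviation: baseline + tilt + two smooth random bumps,
          # the same shape family as the class signatures
          jb1 <- rnorm(1, 0, 1.2 * spec$within_class_sd) *
            exp(-(x - runif(1))^2 / (2 * 0.08^2))
          jb2 <- rnorm(1, 0, 1.2 * spec$within_class_sd) *
            exp(-(x - runif(1))^2 / (2 * 0.08^2))
          sp <- spec$class_spectra[cls, ] +
            rnorm(1, 0, spec$within_class_sd) +
            rnorm(1, 0, spec$within_class_sd) * tilt + jb1 + jb2
          vals <- matrix(sp, npix, B, byrow = TRUE) +
            matrix(rnorm(npix * B, 0, spec$pixel_noise_sd), npix, B)
          if (dom == "target") {
            vals <- sweep(vals, 2, spec$domain_gain, "*")
            vals <- sweep(vals, 2, spec$domain_offset + spec$class_offset[cls, ],
                          "+")
          }
          cube <- array(0, c(H, W, B))
          idx <- which(mask)
          for (b in seq_len(B)) cube[idx + (b - 1L) * H * W] <- vals[, b]
          k <- k + 1L
          out[[k]] <- seed_cube(cube, variety = cls - 1L, domain = dom,
                                labeled = TRUE,
                                sample_id = sprintf("%s_c%d_%03d", dom, cls - 1L, i))
        }
      }
    }
    out
  })
  cube_set(cubes)
}
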