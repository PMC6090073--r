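#' Specification of a synthetic neck phantom
#'
#' Describes a radiograph-like head-neck-shoulder silhouette used to
#' exercise the ROI pipeline with known ground truth. The phantom is built
#' in the digital X-ray convention (dense anatomy dark, background bright)
#' and is axis-aligned: a head disc whose centre sits just above the frame
#' (so the skull base fills the top rows, as in a cervical-spine view), a
#' vertical neck band of constant half-width centred on the image, and a
#' shoulder slab below. Intensity structure, expressed as fractions of the
#' full container range in *complement* space (dense = bright):
#'
#' * `background_level_frac` -- air around the patient;
#' * `rim_level_frac` -- a soft-tissue rim forming the outer
#'   `neck_rim_frac` of the neck band on each side, less dense than the
#'   tissue plateau;
#' * `tissue_level_frac` -- the body plateau (head, shoulders, neck
#'   interior);
#' * `bone_level_frac` -- a dense vertebral core of half-width
#'   `bone_core_halfwidth_frac` centred in the neck;
#' * head and shoulder edges fall off linearly to background over
#'   `head_ramp_frac` / `shoulder_ramp_frac` of the width, mimicking the
#'   shrinking projection path near a body outline. The neck edge itself is
#'   sharp so its ground-truth columns are well defined.
#'
#' Additive Gaussian noise with standard deviation
#' `noise_sd_frac * (2^bit_depth - 1)` is applied and clipped to the valid
#' range; the generator is fully reproducible for a fixed `seed`.
#'
#' @param rows,cols Image dimensions (pixels).
#' @param head_radius_frac Head-disc radius as a fraction of `cols`.
#' @param head_center_row_frac Head-disc centre row as a fraction of
#'   `rows`; negative values put the centre above the frame.
#' @param neck_halfwidth_frac Neck half-width as a fraction of `cols`;
#'   must be smaller than both the head radius and the shoulder half-width
#'   (the neck must be the narrowest span).
#' @param neck_rim_frac Width of the soft-tissue rim on each side of the
#'   neck, as a fraction of `cols`.
#' @param bone_core_halfwidth_frac Half-width of the dense vertebral core.
#' @param shoulder_halfwidth_frac Shoulder-slab half-width (fraction of
#'   `cols`).
#' @param neck_top_frac,neck_bottom_frac Row band of the neck (fractions
#'   of `rows`); the shoulder slab starts at `neck_bottom_frac`.
#' @param background_level_frac,rim_level_frac,tissue_level_frac,bone_level_frac
#'   Intensity plateaus in complement space, fractions of the full range,
#'   ordered background < rim < tissue < bone.
#' @param head_ramp_frac,shoulder_ramp_frac Lateral edge fall-off widths
#'   (fractions of `cols`).
#' @param noise_sd_frac Noise standard deviation as a fraction of the full
#'   range.
#' @param bit_depth 8 or 16.
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(rows = 512L, cols = 512L,
                         head_radius_frac = 0.44,
                         head_center_row_frac = -0.078,
                         neck_halfwidth_frac = 0.22,
                         neck_rim_frac = 0.025,
                         bone_core_halfwidth_frac = 0.06,
                         shoulder_halfwidth_frac = 0.455,
                         neck_top_frac = 0.12,
                         neck_bottom_frac = 0.72,
                         background_level_frac = 0.05,
                         rim_level_frac = 0.51,
                         tissue_level_frac = 0.65,
                         bone_level_frac = 0.86,
                         head_ramp_frac = 0.03,
                         shoulder_ramp_frac = 0.06,
                         noise_sd_frac = 0.02,
                         bit_depth = 8L,
                         seed = 1L) {
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               head_radius_frac = head_radius_frac,
               head_center_row_frac = head_center_row_frac,
               neck_halfwidth_frac = neck_halfwidth_frac,
               neck_rim_frac = neck_rim_frac,
               bone_core_halfwidth_frac = bone_core_halfwidth_frac,
               shoulder_halfwidth_frac = shoulder_halfwidth_frac,
               neck_top_frac = neck_top_frac,
               neck_bottom_frac = neck_bottom_frac,
               background_level_frac = background_level_frac,
               rim_level_frac = rim_level_frac,
               tissue_level_frac = tissue_level_frac,
               bone_level_frac = bone_level_frac,
               head_ramp_frac = head_ramp_frac,
               shoulder_ramp_frac = shoulder_ramp_frac,
               noise_sd_frac = noise_sd_frac,
               bit_depth = as.integer(bit_depth),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$rows < 16L || s$cols < 16L) {
    stop("phantom dimensions must be at least 16 x 16", call. = FALSE)
  }
  if (!s$bit_depth %in% c(8L, 16L)) {
    stop("phantom bit_depth must be 8 or 16", call. = FALSE)
  }
  if (s$neck_halfwidth_frac >= s$shoulder_halfwidth_frac) {
    stop("invalid phantom spec: the neck must be narrower than the shoulders",
         call. = FALSE)
  }
  if (s$neck_halfwidth_frac >= s$head_radius_frac) {
    stop("invalid phantom spec: the neck must be narrower than the head",
         call. = FALSE)
  }
  if (s$bone_core_halfwidth_frac >= s$neck_halfwidth_frac) {
    stop("invalid phantom spec: the bone core must fit inside the neck",
         call. = FALSE)
  }
  lv <- c(s$background_level_frac, s$rim_level_frac,
          s$tissue_level_frac, s$bone_level_frac)
  if (any(lv < 0) || any(lv > 1) || any(diff(lv) <= 0)) {
    stop("invalid phantom spec: levels must satisfy 0 <= background < rim < tissue < bone <= 1",
         call. = FALSE)
  }
  if (s$neck_top_frac >= s$neck_bottom_frac || s$neck_top_frac < 0 ||
      s$neck_bottom_frac > 1) {
    stop("invalid phantom spec: neck row band must satisfy 0 <= top < bottom <= 1",
         call. = FALSE)
  }
  if (s$noise_sd_frac < 0 || s$noise_sd_frac > 0.2) {
    stop("invalid phantom spec: noise_sd_frac must lie in [0, 0.2]",
         call. = FALSE)
  }
  invisible(s)
}

#' Generate a synthetic neck phantom
#'
#' Renders the silhouette described by a [phantom_spec()] and returns the
#' image together with the ground-truth neck columns: `neck_left` and
#' `neck_right` are the outermost columns of the neck band (0-based,
#' inclusive), the span the pipeline's detected bounds are compared
#' against. Identical specs produce byte-identical images.
#'
#' @param spec A [phantom_spec()].
#' @return A `cerv_phantom` list: `image` (a [gray_image] in digital X-ray
#'   convention), `neck_left`, `neck_right`, and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(rows = 128, cols = 128, seed = 42))
#' c(ph$neck_left, ph$neck_right)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  validate_phantom_spec(spec)
  nr <- spec$rows
  nc <- spec$cols
  cc <- (nc - 1) / 2
  r0 <- seq_len(nr) - 1
  d <- abs(seq_len(nc) - 1 - cc)              # column distance from centre
  dmat <- matrix(d, nr, nc, byrow = TRUE)

  bg <- spec$background_level_frac
  rim <- spec$rim_level_frac
  tis <- spec$tissue_level_frac
  bone <- spec$bone_level_frac
  level <- matrix(bg, nr, nc)

  ramp_edge <- function(dist, half, ramp) {
    # plateau inside, linear fall-off to background over `ramp` pixels
    inside <- dist <= pmax(half, 0)
    frac <- pmin(pmax((half - dist) / max(ramp, 1e-9), 0), 1)
    ifelse(inside, bg + (tis - bg) * frac, -Inf)
  }

  # head: disc, centre possibly above the frame
  hr <- spec$head_center_row_frac * nr
  rad <- spec$head_radius_frac * nc
  ch <- ifelse(abs(r0 - hr) <= rad, sqrt(pmax(rad^2 - (r0 - hr)^2, 0)), -Inf)
  level <- pmax(level, ramp_edge(dmat, matrix(ch, nr, nc),
                                 spec$head_ramp_frac * nc))

  # shoulders: constant slab below the neck band
  top_sh <- round(spec$neck_bottom_frac * nr)
  sh_half <- ifelse(r0 >= top_sh, spec$shoulder_halfwidth_frac * nc, -Inf)
  level <- pmax(level, ramp_edge(dmat, matrix(sh_half, nr, nc),
                                 spec$shoulder_ramp_frac * nc))

  # neck band: sharp-edged; soft rim outside, tissue inside, bone core
  hw <- spec$neck_halfwidth_frac * nc
  rim_w <- spec$neck_rim_frac * nc
  core <- spec$bone_core_halfwidth_frac * nc
  r_top <- round(spec$neck_top_frac * nr)
  in_rows <- r0 >= r_top & r0 <= top_sh
  neck_lv <- ifelse(dmat <= core, bone,
                    ifelse(dmat <= hw - rim_w, tis,
                           ifelse(dmat <= hw, rim, -Inf)))
  neck_lv[!in_rows, ] <- -Inf
  level <- pmax(level, neck_lv)

  lim <- bitwShiftL(1L, spec$bit_depth) - 1L
  clean <- (1 - level) * lim                  # back to X-ray convention
  pix <- withr::with_seed(spec$seed, {
    noisy <- clean + stats::rnorm(length(clean), 0, spec$noise_sd_frac * lim)
    round(pmin(pmax(noisy, 0), lim))
  })
  img <- gray_image(matrix(pix, nr, nc), spec$bit_depth)

  structure(list(
    image = img,
    neck_left = as.integer(ceiling(cc - hw)),
    neck_right = as.integer(floor(cc + hw)),
    spec = spec
  ), class = "cerv_phantom")
}

#' @export
print.cerv_phantom <- function(x, ...) {
  cat(sprintf("<cerv_phantom> %d x %d, %d-bit, neck cols %d..%d (seed %d)\n",
              x$spec$rows, x$spec$cols, x$spec$bit_depth,
              x$neck_left, x$neck_right, x$spec$seed))
  invisible(x)
}

#' Generate a suite of phantoms spanning the method's reduction band
#'
#' Draws `n` neck half-widths evenly spanning 0.215-0.335 of the image
#' width (with a small seeded jitter), so the full-height crops remove
#' roughly 30-60 % of the pixels across the suite, and renders one phantom
#' per half-width at each requested bit depth. Phantoms at different depths
#' with the same index share geometry and noise seed, which is what the
#' depth-independence checks compare.
#'
#' @param n Number of geometries (at each depth).
#' @param seed Integer seed controlling the half-width jitter and the
#'   per-phantom noise seeds.
#' @param bit_depths Integer vector, subset of `c(8, 16)`.
#' @param rows,cols Phantom dimensions.
#' @return A list of `cerv_phantom` objects, geometries varying fastest;
#'   each element carries `index` (geometry id) in addition to the usual
#'   fields.
#' @export
generate_suite <- function(n, seed = 7L, bit_depths = 8L,
                           rows = 512L, cols = 512L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!all(bit_depths %in% c(8L, 16L))) {
    stop("`bit_depths` must be a subset of c(8, 16)", call. = FALSE)
  }
  draws <- withr::with_seed(as.integer(seed), {
    hw <- seq(0.215, 0.335, length.out = n) + stats::runif(n, -0.004, 0.004)
    list(hw = hw, seeds = sample.int(.Machine$integer.max %/% 2L, n))
  })
  out <- list()
  for (depth in as.integer(bit_depths)) {
    for (i in seq_len(n)) {
      ph <- generate_phantom(phantom_spec(
        rows = rows, cols = cols,
        neck_halfwidth_frac = draws$hw[i],
        bit_depth = depth, seed = draws$seeds[i]
      ))
      ph$index <- i
      out[[length(out) + 1L]] <- ph
    }
  }
  out
}
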