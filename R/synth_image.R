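#' Nucleus/cytoplasm density presets
#'
#' Named N/C density-ratio presets used by the imaging stage's synthetic
#' cohorts: `control` 1.30, `-AA` 0.25, `-AA+YWF` 2.66, `-AA+LMB` 2.36 —
#' the proteasome-distribution regimes of amino-acid-starved
#' cardiomyocytes (nuclear retention, cytoplasmic export, and nuclear
#' sequestration respectively).
#'
#' @return Named numeric vector of N/C ratios.
#' @export
nc_presets <- function() {
  c("control" = 1.30, "-AA" = 0.25, "-AA+YWF" = 2.66, "-AA+LMB" = 2.36)
}

#' Generate a two-channel synthetic cell image with known N/C ratio
#'
#' The cell is an ellipse, the nucleus a disk strictly inside it. The
#' nuclear-stain channel is nonzero only on the nucleus; the signal channel
#' has expected per-pixel intensity `rho_c = mean_intensity` on the
#' cytoplasm and `rho_n = nc_ratio * rho_c` on the nucleus. Ground truth
#' stores the masks and densities.
#'
#' @param nc_ratio Nucleus/cytoplasm density ratio (> 0), or a preset name
#'   from [nc_presets()] passed via `preset`.
#' @param preset Optional preset name; overrides `nc_ratio`.
#' @param size Image side length in pixels (square image).
#' @param cell_axes Semi-axes of the cell ellipse (pixels).
#' @param nucleus_radius Nucleus disk radius (pixels).
#' @param nucleus_offset Offset of the nucleus centre from the cell centre.
#' @param mean_intensity Expected cytoplasm signal intensity (arbitrary
#'   linear units).
#' @param nuc_channel_intensity Nuclear-stain intensity on the nucleus.
#' @param noise_model `"gaussian"` (SD = `noise_frac * mean_intensity`) or
#'   `"poisson"` (per-pixel Poisson counts at the expected intensity).
#' @param noise_frac Gaussian noise fraction.
#' @param seed Integer seed.
#'
#' @return List with `pair` (class `cell_image_pair`: matrices `nuclear`
#'   and `signal`) and `truth` (masks, densities, `nc_ratio`).
#' @export
gen_cell_image <- function(nc_ratio = 1.0, preset = NULL, size = 128,
                           cell_axes = c(42, 30), nucleus_radius = 12,
                           nucleus_offset = c(5, 0), mean_intensity = 100,
                           nuc_channel_intensity = 200,
                           noise_model = c("gaussian", "poisson"),
                           noise_frac = 0.05, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (!is.null(preset)) {
    if (!preset %in% names(nc_presets())) stop("unknown preset: ", preset)
    nc_ratio <- unname(nc_presets()[preset])
  }
  if (nc_ratio <= 0) stop("nc_ratio must be > 0")
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  cell <- ((xs - cx) / cell_axes[1])^2 + ((ys - cy) / cell_axes[2])^2 <= 1
  nx <- cx + nucleus_offset[1]; ny <- cy + nucleus_offset[2]
  nucleus <- (xs - nx)^2 + (ys - ny)^2 <= nucleus_radius^2
  # the nucleus (dilated by 1 px) must sit strictly inside the cell
  ring <- (xs - nx)^2 + (ys - ny)^2 <= (nucleus_radius + 1)^2
  if (any(ring & !cell)) stop("nucleus not strictly inside the cell")
  cyto <- cell & !nucleus
  rho_c <- mean_intensity
  rho_n <- nc_ratio * rho_c
  sig_mean <- matrix(0, size, size)
  sig_mean[cyto] <- rho_c
  sig_mean[nucleus] <- rho_n
  nuc_mean <- matrix(0, size, size)
  nuc_mean[nucleus] <- nuc_channel_intensity
  with_seed(seed, {
    if (noise_model == "gaussian" && noise_frac > 0) {
      sig <- sig_mean + matrix(stats::rnorm(size^2, 0, noise_frac * mean_intensity), size)
      nuc <- nuc_mean + matrix(stats::rnorm(size^2, 0, noise_frac * nuc_channel_intensity), size)
    } else if (noise_model == "poisson") {
      sig <- matrix(stats::rpois(size^2, as.vector(sig_mean)), size)
      nuc <- matrix(stats::rpois(size^2, as.vector(nuc_mean)), size)
    } else {
      sig <- sig_mean; nuc <- nuc_mean
    }
    pair <- structure(list(nuclear = nuc, signal = sig), class = "cell_image_pair")
    list(pair = pair,
         truth = list(nc_ratio = nc_ratio, rho_n = rho_n, rho_c = rho_c,
                      nucleus_mask = nucleus, cell_mask = cell,
                      cytoplasm_mask = cyto))
  })
}

#' @export
print.cell_image_pair <- function(x, ...) {
  cat(sprintf("<cell_image_pair> %d x %d px, channels: nuclear, signal\n",
              nrow(x$signal), ncol(x$signal)))
  invisible(x)
}

#' Read a registered two-channel image pair from files
#'
#' Accepts one TIFF/PNG file per channel, or a single two-page TIFF
#' (page 1 = nuclear stain, page 2 = signal). Needs the `tiff` / `png`
#' packages for the respective formats.
#'
#' @param nuclear_path Path to the nuclear-channel image (or the two-page
#'   TIFF when `signal_path` is `NULL`).
#' @param signal_path Path to the signal-channel image, or `NULL`.
#' @return A `cell_image_pair`.
#' @export
read_image_pair <- function(nuclear_path, signal_path = NULL) {
  read1 <- function(p) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF needs the 'tiff' package")
      tiff::readTIFF(p, all = TRUE)
    } else if (grepl("\\.png$", p, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG needs the 'png' package")
      list(png::readPNG(p))
    } else stop("unsupported image format: ", p)
  }
  as_gray <- function(m) if (length(dim(m)) == 3L) m[, , 1L] else m
  if (is.null(signal_path)) {
    pages <- read1(nuclear_path)
    if (length(pages) < 2L)
      stop("single-file input must be a two-page TIFF")
    nuc <- as_gray(pages[[1L]]); sig <- as_gray(pages[[2L]])
  } else {
    nuc <- as_gray(read1(nuclear_path)[[1L]])
    sig <- as_gray(read1(signal_path)[[1L]])
  }
  if (!all(dim(nuc) == dim(sig)))
    stop("channel images must have the same shape")
  structure(list(nuclear = nuc, signal = sig), class = "cell_image_pair")
}
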