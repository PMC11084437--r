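#' Segment nucleus, cell and cytoplasm from a two-channel image
#'
#' The nucleus is the largest connected component above `nuc_threshold` in
#' the nuclear-stain channel (holes filled); the cell is the largest
#' component above `cell_threshold` in the signal channel that contains
#' the nucleus (holes filled); the cytoplasm is the cell minus the
#' nucleus. Thresholds are fixed per-dataset constants — the analysis
#' convention is a single constant threshold across all cells of a
#' dataset — and are never chosen adaptively; [suggest_threshold()] can
#' propose a value from the intensity histogram but does not apply it.
#'
#' @param pair A `cell_image_pair` (see [gen_cell_image()],
#'   [read_image_pair()]).
#' @param nuc_threshold Nuclear-channel threshold.
#' @param cell_threshold Signal-channel threshold.
#' @return List of logical masks `nucleus`, `cell`, `cytoplasm`.
#' @export
segment_cell <- function(pair, nuc_threshold, cell_threshold) {
  stopifnot(inherits(pair, "cell_image_pair"))
  if (!all(dim(pair$nuclear) == dim(pair$signal)))
    stop("channels must be registered (same shape)")
  largest_cc <- function(bin, must_contain = NULL) {
    if (!any(bin)) return(NULL)
    lab <- EBImage::bwlabel(bin)
    if (!is.null(must_contain)) {
      ids <- setdiff(unique(lab[must_contain]), 0)
      if (!length(ids)) return(NULL)
    } else ids <- setdiff(unique(as.vector(lab)), 0)
    sizes <- tabulate(lab[lab > 0])
    id <- ids[which.max(sizes[ids])]
    EBImage::fillHull(lab == id) > 0
  }
  nucleus <- largest_cc(pair$nuclear > nuc_threshold)
  if (is.null(nucleus)) stop("empty nucleus mask at threshold ", nuc_threshold)
  cell <- largest_cc(pair$signal > cell_threshold, must_contain = nucleus)
  if (is.null(cell)) stop("no cell component contains the nucleus at threshold ",
                          cell_threshold)
  if (!all(cell[nucleus]))
    stop("nucleus not contained in the cell mask")
  cyto <- cell & !nucleus
  if (!any(cyto)) stop("empty cytoplasm mask")
  list(nucleus = nucleus, cell = cell, cytoplasm = cyto)
}

#' Suggest a nuclear-channel threshold from the intensity histogram
#'
#' Midpoint between the background and foreground modes (2-means on the
#' intensities). Advisory only — segmentation always uses the threshold
#' the caller passes.
#'
#' @param channel Numeric image matrix.
#' @return Suggested threshold value.
#' @export
suggest_threshold <- function(channel) {
  km <- stats::kmeans(as.vector(channel), centers = 2L, nstart = 5L)
  mean(km$centers)
}

#' Measure nucleus/cytoplasm signal density and their ratio
#'
#' Densities follow the raw-integrated-density convention: the summed
#' signal-channel intensity over a compartment mask divided by the
#' compartment area in pixels; the N/C ratio is the nuclear density over
#' the cytoplasmic density.
#'
#' @param pair A `cell_image_pair`.
#' @param masks Masks from [segment_cell()].
#' @return A `cell_density_measurement`: `raw_int_den_nucleus`,
#'   `raw_int_den_cytoplasm`, `area_nucleus_px`, `area_cytoplasm_px`,
#'   `density_n`, `density_c`, `nc_ratio` (NA with a warning when the
#'   cytoplasmic density is zero).
#' @export
measure_nc_ratio <- function(pair, masks) {
  stopifnot(inherits(pair, "cell_image_pair"))
  if (any(masks$nucleus & masks$cytoplasm))
    stop("nucleus and cytoplasm masks overlap")
  a_n <- sum(masks$nucleus); a_c <- sum(masks$cytoplasm)
  if (a_n == 0 || a_c == 0) stop("empty compartment mask")
  rid_n <- sum(pair$signal[masks$nucleus])
  rid_c <- sum(pair$signal[masks$cytoplasm])
  d_n <- rid_n / a_n; d_c <- rid_c / a_c
  nc <- if (d_c == 0) {
    warning("zero cytoplasmic density; N/C ratio set NA")
    NA_real_
  } else d_n / d_c
  structure(list(raw_int_den_nucleus = rid_n, raw_int_den_cytoplasm = rid_c,
                 area_nucleus_px = a_n, area_cytoplasm_px = a_c,
                 density_n = d_n, density_c = d_c, nc_ratio = nc),
            class = "cell_density_measurement")
}

#' @export
print.cell_density_measurement <- function(x, ...) {
  cat(sprintf("<cell_density_measurement> N/C = %.3f (density N %.2f / C %.2f; areas %d / %d px)\n",
              x$nc_ratio, x$density_n, x$density_c,
              x$area_nucleus_px, x$area_cytoplasm_px))
  invisible(x)
}

#' Per-group summary of N/C measurements
#'
#' @param nc_ratios Numeric vector of per-cell N/C ratios.
#' @param groups Group label per cell.
#' @return A [cohort_table()]-compatible summary data.frame with `group`,
#'   `mean`, `sd` (sample SD), `n`; empty groups are skipped with a
#'   warning.
#' @export
cohort_nc_summary <- function(nc_ratios, groups) {
  stopifnot(length(nc_ratios) == length(groups))
  gl <- unique(as.character(groups))
  rows <- list()
  for (g in gl) {
    x <- nc_ratios[groups == g & is.finite(nc_ratios)]
    if (!length(x)) {
      warning("group '", g, "' has no finite measurements; skipped")
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(group = g, mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  do.call(rbind, rows)
}

#' Write segmentation masks as 0/255 PNG images
#'
#' @param masks Masks from [segment_cell()].
#' @param prefix Output path prefix; files `<prefix>_nucleus.png` etc. are
#'   written. Needs the `png` package.
#' @return Invisibly, the written paths.
#' @export
write_masks <- function(masks, prefix) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing masks needs the 'png' package")
  paths <- character()
  for (nm in names(masks)) {
    p <- paste0(prefix, "_", nm, ".png")
    png::writePNG(masks[[nm]] * 1.0, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
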