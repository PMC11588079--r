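#' Triangle-method histogram threshold
#'
#' Geometric thresholding: a line is drawn from the histogram peak to the
#' far end of its longer tail, and the threshold is placed at the bin
#' maximizing the distance between histogram and line. Robust for
#' unimodal histograms with a shoulder, as in transmitted-light images of
#' a dark object on a bright background. Scale-invariant: depends only on
#' the histogram shape.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param n_bins Histogram resolution (default 256).
#' @return The threshold intensity (a bin center).
#' @export
triangle_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite intensities", call. = FALSE)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- graphics::hist(v, breaks = seq(r[1], r[2], length.out = n_bins + 1),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  i_peak <- which.max(counts)
  nz <- which(counts > 0)
  i_lo <- nz[1]; i_hi <- nz[length(nz)]
  # put the longer tail to the right of the peak
  flip <- (i_peak - i_lo) > (i_hi - i_peak)
  if (flip) { counts <- rev(counts); i_peak <- n_bins + 1L - i_peak
              i_hi <- n_bins + 1L - i_lo }
  if (i_hi <= i_peak) return(mids[if (flip) n_bins + 1L - i_peak else i_peak])
  idx <- i_peak:i_hi
  # distance from (idx, counts) to the peak-to-tail chord
  x1 <- i_peak; y1 <- counts[i_peak]; x2 <- i_hi; y2 <- counts[i_hi]
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1)
  i_thr <- idx[which.max(d)]
  if (flip) i_thr <- n_bins + 1L - i_thr
  mids[i_thr]
}

#' Generate a cell ROI from the first brightfield frame
#'
#' Gaussian smoothing (default SD 21 px), triangle thresholding (the cell
#' is darker than the background), morphological closing with a
#' disk-shaped structuring element (default 51 px diameter) to fill holes,
#' and retention of the largest connected component.
#'
#' @param frame Grayscale 2D matrix (`[x, y]`).
#' @param sigma_px Gaussian smoothing SD in pixels.
#' @param close_diameter_px Diameter of the closing disk in pixels.
#' @param dark_foreground If `TRUE` (default) the ROI is the
#'   below-threshold region.
#' @return A logical `roi_mask` matrix with attribute
#'   `provenance = "generated"`.
#' @export
generate_roi <- function(frame, sigma_px = 21, close_diameter_px = 51,
                         dark_foreground = TRUE) {
  if (!is.matrix(frame)) stop("frame must be a 2D matrix", call. = FALSE)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(frame), sigma = sigma_px))
  thr <- triangle_threshold(sm)
  mask <- if (dark_foreground) sm < thr else sm > thr
  if (!any(mask))
    stop("thresholding produced an empty mask: no foreground found",
         call. = FALSE)
  brush <- EBImage::makeBrush(close_diameter_px, shape = "disc")
  mask <- as.matrix(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labs <- as.matrix(lab)
  tab <- tabulate(labs[labs > 0])
  roi <- labs == which.max(tab)
  attr(roi, "provenance") <- "generated"
  roi
}

#' Background statistics and area threshold
#'
#' Computes the mean and SD of the pixels outside the ROI and the area
#' threshold `mean - 1 * SD`: ROI pixels darker than this are counted as
#' chloroplast material.
#'
#' @param frame Grayscale 2D matrix.
#' @param roi Logical ROI mask of the same dimensions.
#' @return A list with `bg_mean`, `bg_sd`, `threshold`.
#' @export
background_threshold <- function(frame, roi) {
  if (!all(dim(frame) == dim(roi)))
    stop("frame and roi dimensions differ", call. = FALSE)
  bg <- frame[!roi]
  if (length(bg) == 0L)
    stop("ROI covers the whole frame: no background pixels", call. = FALSE)
  m <- mean(bg); s <- stats::sd(bg)
  if (is.na(s)) s <- 0
  list(bg_mean = m, bg_sd = s, threshold = m - s)
}

#' Projected chloroplast area over time
#'
#' Counts, per frame, the ROI pixels darker than the background-derived
#' threshold (held fixed over the series).
#'
#' @param series A `brightfield_series`, a list of frames, or a 3D array
#'   `[x, y, t]`.
#' @param roi Logical ROI mask.
#' @param threshold Intensity threshold from [background_threshold()].
#' @param pixel_size Optional pixel size (um/px) to add calibrated areas.
#' @return A data frame with `frame`, `area_px` and (if calibrated)
#'   `area_um2`, plus `relative_area` normalized to the first frame.
#' @export
area_trace <- function(series, roi, threshold, pixel_size = NULL) {
  frames <- series_frames(series)
  a <- vapply(frames, function(f) sum(f[roi] < threshold), numeric(1))
  out <- data.frame(frame = seq_along(a), area_px = a,
                    relative_area = if (a[1] > 0) a / a[1] else NA_real_)
  if (!is.null(pixel_size)) out$area_um2 <- a * pixel_size^2
  out
}

#' Relative light-loss trace
#'
#' The loss `dI(t) = Ibg(t) - I(t)` is the background intensity (mean in a
#' background ROI outside the cell) minus the mean transmitted intensity
#' in the cell ROI; the loss ratio `dI(t)/dI(0)` is its value relative to
#' the first frame. A decreasing loss ratio means more light passes
#' through the cell (chloroplast retracted).
#'
#' @param series A `brightfield_series`, list of frames, or `[x, y, t]`
#'   array.
#' @param roi Logical cell ROI.
#' @param bg_roi Logical background ROI, disjoint from `roi`.
#' @return A data frame with `frame`, `I_roi`, `I_bg`, `loss`,
#'   `loss_ratio`.
#' @export
loss_trace <- function(series, roi, bg_roi) {
  if (any(roi & bg_roi))
    stop("background ROI must be disjoint from the cell ROI", call. = FALSE)
  frames <- series_frames(series)
  I_roi <- vapply(frames, function(f) mean(f[roi]), numeric(1))
  I_bg <- vapply(frames, function(f) mean(f[bg_roi]), numeric(1))
  loss <- I_bg - I_roi
  if (loss[1] <= 0)
    stop("initial loss is not positive: cell is not darker than background",
         call. = FALSE)
  data.frame(frame = seq_along(loss), I_roi = I_roi, I_bg = I_bg,
             loss = loss, loss_ratio = loss / loss[1])
}

series_frames <- function(series) {
  if (inherits(series, "brightfield_series")) return(series$frames)
  if (is.list(series)) return(series)
  if (is.array(series) && length(dim(series)) == 3L)
    return(lapply(seq_len(dim(series)[3]), function(t) series[, , t]))
  stop("cannot interpret object as an image series", call. = FALSE)
}
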