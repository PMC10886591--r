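# Automated morphometry of fibrin network images: binarization, percent
# area covered, inscribed-circle pore diameters, skeleton fiber segment
# lengths. A deterministic stand-in for manual line-tool measurements,
# validated against synthetic ground truth.

#' Construct a network image
#'
#' @param pixels 2-D numeric matrix of grayscale intensities (a single
#'   confocal plane).
#' @param pixel_size physical pixel size, micrometers per pixel (> 0).
#' @param channel label.
#' @return list of class `network_image`.
#' @export
network_image <- function(pixels, pixel_size, channel = "") {
  if (!is.matrix(pixels)) abort_cq("pixels must be a 2-D matrix", "cq_bad_image")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    abort_cq("pixel_size must be > 0 um/px", "cq_bad_image")
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel),
            class = "network_image")
}

#' Read a grayscale network image from TIFF/PNG
#'
#' Multi-channel images are averaged to one grayscale plane.
#'
#' @param path image file.
#' @param pixel_size micrometers per pixel.
#' @return a [network_image()].
#' @export
read_network_image <- function(path, pixel_size) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  network_image(as.matrix(px), pixel_size)
}

#' Binarize a network image
#'
#' Foreground (TRUE) = fibers. `otsu` chooses the threshold that minimizes
#' intra-class intensity variance; `fixed` applies a user threshold on the
#' image's own intensity scale.
#'
#' @param image a [network_image()] or numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold for `fixed`, in the image intensity units.
#' @return logical matrix mask.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- if (inherits(image, "network_image")) image$pixels else image
  rng <- range(px)
  if (method == "fixed") {
    if (is.null(threshold)) abort_cq("fixed method needs a threshold",
                                     "cq_bad_threshold")
    return(px > threshold)
  }
  if (diff(rng) == 0)
    abort_cq("constant image: Otsu is undefined, use method = 'fixed'",
             "cq_constant_image")
  scaled <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  scaled > thr
}

#' Percent area covered by fibers
#'
#' @param mask logical matrix (TRUE = fiber).
#' @return percentage of foreground pixels, 0-100.
#' @export
percent_area <- function(mask) {
  if (!length(mask)) abort_cq("empty mask", "cq_bad_image")
  100 * sum(mask) / length(mask)
}

#' Pore diameters by largest inscribed circle
#'
#' Each pore is a connected background region not touching the image border
#' (border pores are censored by the field of view). The pore diameter is
#' twice the maximum of the Euclidean distance transform inside the pore —
#' the diameter of the largest inscribed circle, emulating a line-tool
#' measurement of the average pore width.
#'
#' @param mask logical matrix (TRUE = fiber).
#' @param pixel_size micrometers per pixel.
#' @return list with `diameters` (um, one per pore) and `mean`.
#' @export
pore_sizes <- function(mask, pixel_size) {
  bg <- !mask
  if (!any(bg)) return(list(diameters = numeric(0), mean = NA_real_))
  lab <- EBImage::bwlabel(matrix(as.numeric(bg), nrow(bg), ncol(bg)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  keep <- setdiff(seq_len(max(lab)), border_labels)
  if (!length(keep)) {
    warning("no interior pores found")
    return(list(diameters = numeric(0), mean = NA_real_))
  }
  dist <- EBImage::distmap(matrix(as.numeric(bg), nrow(bg), ncol(bg)))
  d <- vapply(keep, function(k) 2 * max(dist[lab == k]) * pixel_size,
              numeric(1))
  list(diameters = d, mean = mean(d))
}

#' Fiber segment lengths from the mask skeleton
#'
#' The foreground is thinned to a one-pixel skeleton, split at branch
#' points, and each remaining segment's path length (diagonal steps weighted
#' sqrt(2)) is converted to micrometers. Thinning erodes roughly half the
#' fiber width from each free end, so the distance-transform value at each
#' true skeleton endpoint (its local half-width) is added back. Short spur
#' segments below `min_length_px` are discarded.
#'
#' @param mask logical matrix (TRUE = fiber).
#' @param pixel_size micrometers per pixel.
#' @param min_length_px minimum segment length in pixels (default 3).
#' @return list with `lengths` (um per segment) and `mean`.
#' @export
fiber_lengths <- function(mask, pixel_size, min_length_px = 3) {
  if (!any(mask)) return(list(lengths = numeric(0), mean = NA_real_))
  skel <- skeletonize(mask)
  if (!any(skel)) {
    warning("foreground vanished under thinning")
    return(list(lengths = numeric(0), mean = NA_real_))
  }
  nb <- neighbor_count(skel)
  segs <- skel & !(skel & nb >= 3)
  if (!any(segs)) return(list(lengths = numeric(0), mean = NA_real_))
  lab <- label8(segs)
  len_px <- component_lengths_px(lab)
  # End correction: free endpoints of the full skeleton get their local
  # half-width back (distance transform of the mask at the endpoint).
  ep <- which(segs & nb <= 1)
  if (length(ep)) {
    dist <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    corr <- rowsum(dist[ep], lab[ep])
    len_px[as.integer(rownames(corr))] <-
      len_px[as.integer(rownames(corr))] + corr[, 1]
  }
  len_px <- len_px[len_px >= min_length_px]
  if (!length(len_px)) return(list(lengths = numeric(0), mean = NA_real_))
  lengths <- len_px * pixel_size
  list(lengths = lengths, mean = mean(lengths))
}

#' Quantify a network image
#'
#' Composes binarization, percent area, pore sizing and fiber segment
#' measurement under one configuration. Component failures are recorded in
#' `flag` instead of aborting.
#'
#' @param image a [network_image()].
#' @param method,threshold see [binarize()].
#' @param invert analyse the complement of the mask (for inverted-contrast
#'   images).
#' @param min_length_px see [fiber_lengths()].
#' @return list of class `structure_metrics`: `percent_area`,
#'   `pore_diameters`, `pore_mean`, `fiber_segment_lengths`, `fiber_mean`,
#'   `flag`.
#' @export
quantify <- function(image, method = "otsu", threshold = NULL,
                     invert = FALSE, min_length_px = 3) {
  stopifnot(inherits(image, "network_image"))
  flag <- ""
  mask <- tryCatch(binarize(image, method, threshold),
                   error = function(e) { flag <<- conditionMessage(e); NULL })
  if (is.null(mask))
    return(structure(list(percent_area = NA_real_,
                          pore_diameters = numeric(0), pore_mean = NA_real_,
                          fiber_segment_lengths = numeric(0),
                          fiber_mean = NA_real_, flag = flag),
                     class = "structure_metrics"))
  if (invert) mask <- !mask
  pores <- withCallingHandlers(
    pore_sizes(mask, image$pixel_size),
    warning = function(w) { flag <<- conditionMessage(w)
                            invokeRestart("muffleWarning") })
  fibers <- withCallingHandlers(
    fiber_lengths(mask, image$pixel_size, min_length_px),
    warning = function(w) { flag <<- conditionMessage(w)
                            invokeRestart("muffleWarning") })
  structure(list(percent_area = percent_area(mask),
                 pore_diameters = pores$diameters, pore_mean = pores$mean,
                 fiber_segment_lengths = fibers$lengths,
                 fiber_mean = fibers$mean, flag = flag),
            class = "structure_metrics")
}
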