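#' A single assay frame with physical geometry attached
#'
#' @param pixels Numeric matrix of greyscale intensities in `[0, 1]`,
#'   rows indexing y (image rows) and columns indexing x.
#' @param t Acquisition time (h).
#' @param pixel_size Isotropic pixel size (um/px).
#' @param geom [domain_geometry()] of the field of view; the pixel grid
#'   must reproduce `lx` x `ly` to within one pixel.
#' @return Object of class `assay_image`.
#' @export
assay_image <- function(pixels, t, pixel_size, geom = domain_geometry()) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (abs(ncol(pixels) * pixel_size - geom$lx) > pixel_size ||
      abs(nrow(pixels) * pixel_size - geom$ly) > pixel_size)
    stop(sprintf(
      "pixel grid (%d x %d at %g um/px) does not reproduce the stated %g x %g um geometry",
      ncol(pixels), nrow(pixels), pixel_size, geom$lx, geom$ly), call. = FALSE)
  structure(list(pixels = pixels, t = t, pixel_size = pixel_size, geom = geom),
            class = "assay_image")
}

#' @export
print.assay_image <- function(x, ...) {
  cat(sprintf("<assay_image> %d x %d px (%g um/px), t = %g h\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$t))
  invisible(x)
}

#' Edge-detection pipeline settings
#'
#' Parameters of the leading-edge detection pipeline: Canny thresholds
#' (`NULL` = automatic: Otsu on the gradient magnitude for the high
#' threshold, low = 0.4 x high), the radius of the disk structuring
#' element used for edge dilation and its reversal (Matlab `strel`
#' convention), the minimum retained vacant component (px), the median
#' smoothing window (px, odd) and the pixel connectivity for component
#' labelling.
#'
#' @param canny_low,canny_high Canny hysteresis thresholds on the
#'   gradient magnitude, or `NULL` for automatic selection.
#' @param canny_sigma Gaussian smoothing sd (px) before gradients.
#' @param dilation_radius Disk radius (px) for edge dilation/erosion.
#' @param min_vacant_component Minimum vacant component size (px) kept.
#' @param median_window Median filter window (px, odd).
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `edge_params`.
#' @export
edge_params <- function(canny_low = NULL, canny_high = NULL,
                        canny_sigma = sqrt(2), dilation_radius = 15,
                        min_vacant_component = 10000, median_window = 3,
                        connectivity = 8) {
  stopifnot(dilation_radius >= 1, min_vacant_component >= 1,
            median_window %% 2 == 1, connectivity %in% c(4, 8))
  structure(list(canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma,
                 dilation_radius = as.integer(dilation_radius),
                 min_vacant_component = as.integer(min_vacant_component),
                 median_window = as.integer(median_window),
                 connectivity = as.integer(connectivity)),
            class = "edge_params")
}

# Median filter of a binary mask = majority vote in the w x w window,
# computed as a box count via 2-D cumulative sums (replicated borders).
binary_median <- function(mask, window) {
  half <- (window - 1L) %/% 2L
  if (half < 1) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2 * half, nc + 2 * half)
  ridx <- pmin(pmax(seq_len(nr + 2 * half) - half, 1), nr)
  cidx <- pmin(pmax(seq_len(nc + 2 * half) - half, 1), nc)
  pad[] <- (mask * 1)[ridx, cidx]
  cs <- apply(rbind(0, pad), 2, cumsum)
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  w <- 2L * half + 1L
  counts <- cs[(w + 1):(nr + w), (w + 1):(nc + w)] -
    cs[1:nr, (w + 1):(nc + w)] - cs[(w + 1):(nr + w), 1:nc] + cs[1:nr, 1:nc]
  counts >= (window * window + 1) / 2
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Connected-component labels; EBImage::bwlabel is 4-connected, so for
# 8-connectivity diagonal label adjacencies are merged by union-find.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (connectivity == 4 || nmax <= 1) return(lab)
  pairs <- NULL
  for (dc in c(-1, 1)) {
    s <- shift_mat(lab, 1, dc)
    sel <- lab > 0 & s > 0 & lab != s
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(lab[sel], s[sel])))
  }
  if (is.null(pairs)) return(lab)
  storage.mode(pairs) <- "integer"
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and hysteresis thresholding (weak-edge
#' components are kept only when they touch a strong edge). Automatic
#' thresholds take the high threshold from Otsu's method applied to the
#' gradient-magnitude histogram and set low = 0.4 x high — a
#' deterministic stand-in for Matlab's unpublished automatic rule.
#'
#' @param img Numeric matrix of intensities in `[0, 1]`.
#' @param params An [edge_params()].
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, params = edge_params()) {
  stopifnot(is.matrix(img))
  sm <- EBImage::gblur(img, sigma = params$canny_sigma)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  ky <- t(kx)                                          # d/dy (rows)
  gx <- EBImage::filter2(sm, kx, boundary = "replicate")
  gy <- EBImage::filter2(sm, ky, boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)

  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (round(ang / (pi / 4))) %% 4   # 0=E, 1=SE, 2=S, 3=SW

  keep <- matrix(FALSE, nrow(img), ncol(img))
  nb <- list(`0` = list(c(0, 1), c(0, -1)),
             `1` = list(c(1, 1), c(-1, -1)),
             `2` = list(c(1, 0), c(-1, 0)),
             `3` = list(c(1, -1), c(-1, 1)))
  for (s in 0:3) {
    sel <- sector == s
    n1 <- shift_mat(mag, nb[[s + 1]][[1]][1], nb[[s + 1]][[1]][2])
    n2 <- shift_mat(mag, nb[[s + 1]][[2]][1], nb[[s + 1]][[2]][2])
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }

  high <- params$canny_high
  low <- params$canny_low
  if (is.null(high)) {
    mmax <- max(mag)
    # a featureless frame has only rounding-level gradients: no edges
    if (mmax <= 1e-6) return(matrix(FALSE, nrow(img), ncol(img)))
    high <- as.numeric(EBImage::otsu(EBImage::Image(mag / mmax))) * mmax
  }
  if (is.null(low)) low <- 0.4 * high

  weak <- keep & mag > low
  strong <- keep & mag > high
  if (!any(strong)) return(strong)
  lab <- label_components(weak, connectivity = 8)
  keep_labels <- unique(lab[strong])
  weak & matrix(lab %in% keep_labels, nrow(img), ncol(img))
}

#' Detect the vacant scratch region in one frame
#'
#' The fixed pipeline of the leading-edge image analysis: (1) Canny edge
#' map; (2) dilation of the edges with a disk of `dilation_radius`; (3)
#' the vacant mask is the complement of the dilated edge map, with vacant
#' connected components smaller than `min_vacant_component` pixels
#' removed (these are gaps within the monolayer, not the scratch); (4)
#' the retained cell-region mask is eroded with the same disk, reversing
#' the dilation; (5) the binary mask is median-filtered; (6) the vacant
#' area is the vacant pixel count times the pixel area. A frame in which
#' no vacant component survives is a closed scratch
#' (`a_vacant_um2 = 0`), not an error.
#'
#' @param image An [assay_image()].
#' @param params An [edge_params()].
#' @return Object of class `vacant_region`: list with `vacant_mask`
#'   (logical matrix), `a_vacant_um2`, `edge_polyline` (tibble `x_um`,
#'   `y_um`, `component`) and `t`.
#' @export
detect_vacant_region <- function(image, params = edge_params()) {
  stopifnot(inherits(image, "assay_image"), inherits(params, "edge_params"))
  px <- image$pixels
  edges <- canny_edges(px, params)
  brush <- EBImage::makeBrush(2L * params$dilation_radius + 1L, shape = "disc")
  dil <- EBImage::dilate(edges * 1, brush)
  vacant <- dil < 0.5

  lab <- label_components(vacant, params$connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_vacant_component)
    vacant <- matrix(lab %in% keep, nrow(px), ncol(px))
  }

  cell_mask <- !vacant
  cell_eroded <- EBImage::erode(cell_mask * 1, brush)
  vacant <- cell_eroded < 0.5
  vacant <- binary_median(vacant, params$median_window)

  a_vacant <- sum(vacant) * image$pixel_size^2
  poly <- if (any(vacant)) {
    oc <- EBImage::ocontour(EBImage::Image(t(vacant * 1)))
    dplyr::bind_rows(lapply(seq_along(oc), function(i)
      tibble::tibble(x_um = (oc[[i]][, 1] + 0.5) * image$pixel_size,
                     y_um = (oc[[i]][, 2] + 0.5) * image$pixel_size,
                     component = i)))
  } else {
    tibble::tibble(x_um = numeric(0), y_um = numeric(0), component = integer(0))
  }
  structure(list(vacant_mask = vacant, a_vacant_um2 = a_vacant,
                 edge_polyline = poly, t = image$t),
            class = "vacant_region")
}

#' @export
print.vacant_region <- function(x, ...) {
  cat(sprintf("<vacant_region> t = %g h, A_vacant = %.4g um^2\n",
              x$t, x$a_vacant_um2))
  invisible(x)
}

#' Scratch half-width from the vacant area
#'
#' Converts a measured vacant area into the half-width of an equivalent
#' rectangular scratch spanning the frame height:
#' `L_E = A_vacant / (2 * ly)`, i.e. the distance from the scratch centre
#' to the leading edge.
#'
#' @param a_vacant Vacant area (um^2), in `[0, lx * ly]`.
#' @param geom A [domain_geometry()].
#' @return Half-width (um); vectorised over `a_vacant`.
#' @examples
#' half_width(500 * 1430) # 250 um
#' @export
half_width <- function(a_vacant, geom = domain_geometry()) {
  # half a per-cent slack: a pixel grid can overcover the nominal
  # geometry by up to one pixel row/column
  if (any(a_vacant < 0) || any(a_vacant > geom$lx * geom$ly * 1.005))
    stop("vacant area must lie in [0, lx * ly]", call. = FALSE)
  pmin(a_vacant / (2 * geom$ly), geom$lx / 2)
}

#' Extract the leading-edge series from an image stack
#'
#' Applies [detect_vacant_region()] and [half_width()] to every frame of
#' a time-sorted stack, returning the per-frame vacant area and
#' half-width.
#'
#' @param stack List of [assay_image()] frames, sorted by time and
#'   sharing one pixel size.
#' @param params An [edge_params()].
#' @param replicate_id Optional replicate label attached to the series.
#' @return Tibble with columns `replicate_id` (if given), `t_h`,
#'   `a_vacant_um2`, `le_um`.
#' @export
extract_leading_edge_series <- function(stack, params = edge_params(),
                                        replicate_id = NULL) {
  stopifnot(is.list(stack), length(stack) >= 1)
  ps <- vapply(stack, function(f) f$pixel_size, numeric(1))
  if (length(unique(ps)) > 1)
    stop("configuration error: mixed pixel sizes within one stack",
         call. = FALSE)
  ts <- vapply(stack, function(f) f$t, numeric(1))
  if (is.unsorted(ts)) stop("frames must be time-sorted", call. = FALSE)
  geom <- stack[[1]]$geom
  res <- lapply(stack, detect_vacant_region, params = params)
  out <- tibble::tibble(
    t_h = ts,
    a_vacant_um2 = vapply(res, function(r) r$a_vacant_um2, numeric(1)))
  out$le_um <- half_width(out$a_vacant_um2, geom)
  if (!is.null(replicate_id))
    out <- dplyr::mutate(out, replicate_id = replicate_id, .before = 1)
  out
}

#' Relative wound density
#'
#' The standard live-imaging readout, for comparison with the mechanistic
#' analysis: the fraction of the initially-scratched region that has been
#' re-occupied by cells at each time,
#' `RWD(t) = 1 - A_vacant(t) / A_vacant(0)`, clipped to `[0, 1]`.
#'
#' @param series Tibble from [extract_leading_edge_series()] (needs
#'   `t_h` and `a_vacant_um2`; the first frame defines the scratch
#'   footprint).
#' @return The input tibble with an added `rwd` column.
#' @export
relative_wound_density <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) >= 1,
            all(c("t_h", "a_vacant_um2") %in% names(series)))
  a0 <- series$a_vacant_um2[which.min(series$t_h)]
  if (a0 <= 0)
    stop("relative wound density undefined: no vacant area in the first frame",
         call. = FALSE)
  dplyr::mutate(series, rwd = pmin(1, pmax(0, 1 - .data$a_vacant_um2 / a0)))
}
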