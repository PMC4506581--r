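rgb_to_grey <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3)
      return(0.2989 * arr[, , 1] + 0.5870 * arr[, , 2] + 0.1140 * arr[, , 3])
    return(arr[, , 1])
  }
  stop("unsupported image array layout", call. = FALSE)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop(sprintf("unsupported image format '%s' for %s", ext, path),
                     call. = FALSE))
  was_rgb <- length(dim(arr)) == 3
  out <- rgb_to_grey(arr)
  if (was_rgb)
    message(sprintf("converted RGB frame to greyscale by luminance weights: %s",
                    basename(path)))
  out
}

parse_frame_time <- function(filename) {
  m <- regmatches(filename, regexec("_t([0-9]+\\.?[0-9]*)\\.[a-zA-Z]+$",
                                    filename))[[1]]
  if (length(m) < 2) return(NA_real_)
  as.numeric(m[2])
}

#' Read a time-stamped image stack
#'
#' Reads assay frames from either (a) a directory of single-frame
#' TIFF/PNG files named `<prefix>_t<hours>.<ext>` (a `times.csv` sidecar
#' with columns `file`, `t_h` overrides filename parsing), or (b) a
#' multi-page TIFF accompanied by `<stem>_times.csv` with a `t_h` column,
#' one row per page. RGB frames are converted to greyscale by the fixed
#' luminance weights 0.2989/0.5870/0.1140. Frames are returned sorted by
#' time with the physical geometry attached.
#'
#' @param path Directory of frames or a multi-page TIFF file.
#' @param pixel_size Isotropic pixel size (um/px) of the frames.
#' @param geom [domain_geometry()] of the field of view.
#' @return List of [assay_image()] frames sorted by time.
#' @export
read_image_stack <- function(path, pixel_size, geom = domain_geometry()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0)
      stop(sprintf("no TIFF/PNG frames found in %s", path), call. = FALSE)
    sidecar <- file.path(path, "times.csv")
    if (file.exists(sidecar)) {
      tab <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
      if (!all(c("file", "t_h") %in% names(tab)))
        stop("times.csv must have columns `file` and `t_h`", call. = FALSE)
      idx <- match(basename(files), tab$file)
      if (anyNA(idx))
        stop("times.csv does not list every frame file", call. = FALSE)
      times <- tab$t_h[idx]
    } else {
      times <- vapply(basename(files), parse_frame_time, numeric(1))
      if (anyNA(times))
        stop(paste("cannot parse acquisition times: name frames",
                   "`<prefix>_t<hours>.<ext>` or provide times.csv"),
             call. = FALSE)
    }
    mats <- lapply(files, read_frame_file)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(tools::file_path_sans_ext(path), "_times.csv")
    if (!file.exists(sidecar))
      stop(sprintf("multi-page TIFF needs a sidecar %s with a t_h column",
                   basename(sidecar)), call. = FALSE)
    tab <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    if (!"t_h" %in% names(tab) || nrow(tab) != length(pages))
      stop("sidecar times CSV must have one `t_h` row per TIFF page",
           call. = FALSE)
    times <- tab$t_h
    mats <- lapply(pages, rgb_to_grey)
  } else {
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  }
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) > 1)
    stop("frames have inconsistent dimensions within one stack", call. = FALSE)
  ord <- order(times)
  lapply(ord, function(i)
    assay_image(mats[[i]], t = times[i], pixel_size = pixel_size, geom = geom))
}

#' Write a synthetic assay to disk
#'
#' Writes the tabular artefacts of a [generate_assay()] result (counts,
#' clean and noisy leading-edge series), the ground-truth manifest, and —
#' when the assay was rendered — per-replicate TIFF stacks with
#' `times.csv` sidecars, so the files can be consumed unchanged by
#' [read_image_stack()] and the estimation functions.
#'
#' @param assay A `synthetic_assay`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assay <- function(assay, dir) {
  stopifnot(inherits(assay, "synthetic_assay"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(assay$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(assay$le_clean, file.path(dir, "le_clean.csv"),
                   row.names = FALSE)
  utils::write.csv(assay$le_noisy, file.path(dir, "le_noisy.csv"),
                   row.names = FALSE)
  gt <- assay$ground_truth
  jsonlite::write_json(
    list(D = gt$params$D, lambda = gt$params$lambda, K = gt$params$K,
         C0 = gt$params$C0, le0 = gt$le0, seed = gt$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(assay$frames)) {
    for (r in seq_along(assay$frames)) {
      rep_dir <- file.path(dir, sprintf("replicate_%d", r))
      dir.create(rep_dir, showWarnings = FALSE)
      stack <- assay$frames[[r]]
      files <- character(length(stack))
      for (i in seq_along(stack)) {
        files[i] <- sprintf("frame_t%g.tif", stack[[i]]$t)
        tiff::writeTIFF(stack[[i]]$pixels, file.path(rep_dir, files[i]),
                        bits.per.sample = 8)
      }
      utils::write.csv(
        data.frame(file = files,
                   t_h = vapply(stack, function(f) f$t, numeric(1))),
        file.path(rep_dir, "times.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a subregion cell-count table
#'
#' Reads a CSV of per-subregion cell counts with columns `t_h`,
#' `n_cells` and optionally `condition`, `replicate_id`, `subregion_id`,
#' validating types on load.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_counts_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_counts(tab)
}

#' Read a leading-edge series table
#'
#' Reads a CSV with columns `t_h`, `le_um` and optionally
#' `replicate_id`, `a_vacant_um2`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_le_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_le_series(tab)
}
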