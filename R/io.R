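#' Read and write count series
#'
#' Counts are stored as a plain CSV with one column per bin (`bin_1..bin_B`)
#' and one row per recorded frame; a JSON sidecar (`<path>.json`) carries
#' the frame interval and any provenance the writer supplies. Round-trips
#' are lossless (integer counts).
#'
#' @param counts A `count_series` tibble.
#' @param path CSV file path.
#' @param provenance Optional named list merged into the sidecar.
#' @export
write_counts <- function(counts, path, provenance = list()) {
  m <- counts_matrix(counts)
  df <- as.data.frame(m)
  names(df) <- paste0("bin_", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(
    list(
      format = "dfft-counts", version = 1L,
      frame_interval = frame_interval(counts),
      n_frames = nrow(m), n_bins = ncol(m)
    ),
    provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_counts
#' @return For `read_counts()`, a `count_series` tibble.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(
      "invalid count at row ", bad[1, 1], ", column '", colnames(m)[bad[1, 2]],
      "': counts must be nonnegative integers",
      call. = FALSE
    )
  }
  fi <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$frame_interval)) fi <- meta$frame_interval
  }
  new_count_series(m, frame_interval = fi)
}

#' Read and write DFFT model files
#'
#' Models are JSON documents with fields `version`, `v`, `f`, `mu`,
#' `n_max` and a `gauge` note; arrays are written at full double precision
#' so round-trips are exact to 1e-15 relative. Files whose frustration
#' violates the `f_0 = f_1 = 0` convention are rejected.
#'
#' @param model A [dfft_model].
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "dfft-model", version = 1L,
    v = model$v, f = model$f, mu = model$mu, n_max = model$n_max,
    gauge = "f_0 = f_1 = 0"
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @return For `read_model()`, a [dfft_model].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("v", "f", "mu")) {
    if (is.null(doc[[field]])) {
      stop("model file is missing field '", field, "'", call. = FALSE)
    }
  }
  if (max(abs(doc$f[1:2])) > 1e-9) {
    stop("gauge violation in model file: f_0 and f_1 must be 0", call. = FALSE)
  }
  dfft_model(doc$v, doc$f, mu = doc$mu)
}

#' Read and write bin lattices
#'
#' Lattices are JSON documents listing bins (`bin`, `x`, `y`, `area`) and
#' adjacency pairs.
#'
#' @param lattice A [bin_lattice].
#' @param path JSON file path.
#' @export
write_lattice <- function(lattice, path) {
  doc <- list(
    format = "dfft-lattice", version = 1L,
    bins = as.data.frame(lattice[, c("bin", "x", "y", "area")]),
    adjacency = as.data.frame(attr(lattice, "adjacency"))
  )
  names(doc$adjacency) <- c("from", "to")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_lattice
#' @return For `read_lattice()`, a [bin_lattice].
#' @export
read_lattice <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$bins)) stop("lattice file is missing 'bins'", call. = FALSE)
  adj <- if (!is.null(doc$adjacency) && length(doc$adjacency)) {
    as.matrix(doc$adjacency)
  } else {
    matrix(integer(0), ncol = 2)
  }
  bin_lattice(doc$bins, adj)
}

#' Bin agent tracks into a count series
#'
#' Assigns each tracked centroid to the bin whose half-open rectangle
#' `[x0, x1) x [y0, y1)` contains it (rectangles are centered on the bin
#' centers with widths equal to the grid spacing), so boundary points
#' belong to exactly one bin and totals are conserved. Points falling
#' outside every bin are tolerated up to 1% and dropped with a message;
#' beyond that the geometry is presumed wrong and binning aborts.
#'
#' @param tracks A data frame with columns `frame`, `id`, `x`, `y`;
#'   (frame, id) pairs must be unique and coordinates finite.
#' @param lattice The target [bin_lattice].
#' @param frame_interval Seconds per frame for the output metadata.
#' @return A `count_series` tibble with one row per frame present in
#'   `tracks` (frames are taken consecutively from min to max).
#' @export
bin_tracks <- function(tracks, lattice, frame_interval = 1) {
  stopifnot(all(c("frame", "id", "x", "y") %in% names(tracks)))
  if (anyDuplicated(tracks[, c("frame", "id")])) {
    stop("duplicate (frame, id) pairs in tracks", call. = FALSE)
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  gx <- snap_to_grid(lattice$x)
  gy <- snap_to_grid(lattice$y)
  hx <- grid_spacing(lattice$x)
  hy <- grid_spacing(lattice$y)
  ix <- floor((tracks$x - (min(lattice$x) - hx / 2)) / hx)
  iy <- floor((tracks$y - (min(lattice$y) - hy / 2)) / hy)
  key <- paste(gx, gy)
  bin_of <- stats::setNames(lattice$bin, key)
  bins <- bin_of[paste(ix, iy)]
  outside <- is.na(bins)
  if (mean(outside) > 0.01) {
    stop(
      sprintf(
        "%.1f%% of track points fall outside the lattice: geometry mismatch",
        100 * mean(outside)
      ),
      call. = FALSE
    )
  }
  if (any(outside)) {
    message(sum(outside), " track point(s) outside the lattice were dropped")
  }
  frames <- seq(min(tracks$frame), max(tracks$frame))
  tab <- table(
    factor(tracks$frame[!outside], levels = frames),
    factor(bins[!outside], levels = lattice$bin)
  )
  new_count_series(unclass(tab), frame_interval = frame_interval)
}

grid_spacing <- function(z) {
  u <- sort(unique(z))
  if (length(u) == 1) 1 else min(diff(u))
}
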