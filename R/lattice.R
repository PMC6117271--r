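#' Bin lattices
#'
#' A bin lattice describes the arena geometry used to discretize a crowd:
#' bin identities, centroid coordinates, areas and which bins are adjacent
#' for move proposals. Bins are the fundamental observation unit (the
#' "quadrats" of spatial count statistics): agents are counted per bin and
#' all inference runs on those counts.
#'
#' Adjacency is stored as a bin-by-direction slot matrix. Each bin has the
#' same number of proposal slots (the maximum degree of the lattice); slots
#' that fall outside the arena are `NA`. A move proposal draws a slot
#' uniformly, so the proposal kernel satisfies q(b -> b') = q(b' -> b) even
#' at boundaries, where the missing-slot proposals are simply rejected.
#'
#' @param bins A data frame with columns `bin` (integer id, 1..B), `x`, `y`
#'   (centroid coordinates) and `area` (positive, same units for all bins).
#' @param neighbors A two-column integer matrix or data frame of adjacent
#'   bin-id pairs; symmetry is enforced, self-pairs are an error.
#' @return An object of class `bin_lattice`: the `bins` tibble with the slot
#'   matrix and adjacency pairs stored as attributes.
#' @examples
#' lat <- quasi1d_lattice(6)
#' n_bins(lat)
#' @export
bin_lattice <- function(bins, neighbors) {
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("bin", "x", "y", "area") %in% names(bins)))
  B <- nrow(bins)
  if (!identical(as.integer(bins$bin), seq_len(B))) {
    stop("`bins$bin` must be the integers 1..B in order", call. = FALSE)
  }
  if (any(bins$area <= 0)) stop("all bin areas must be positive", call. = FALSE)
  if (anyDuplicated(bins[, c("x", "y")])) {
    stop("bin centers must be pairwise distinct", call. = FALSE)
  }
  nb <- as.matrix(neighbors)[, 1:2, drop = FALSE]
  storage.mode(nb) <- "integer"
  if (any(nb[, 1] == nb[, 2])) stop("adjacency must be irreflexive", call. = FALSE)
  if (any(nb < 1L | nb > B)) stop("adjacency refers to unknown bins", call. = FALSE)
  # symmetrize and deduplicate
  nb <- unique(rbind(nb, nb[, 2:1, drop = FALSE]))
  nbr_list <- split(nb[, 2], factor(nb[, 1], levels = seq_len(B)))
  deg <- lengths(nbr_list)
  D <- max(deg, 1L)
  slots <- matrix(NA_integer_, nrow = B, ncol = D)
  for (b in seq_len(B)) {
    if (deg[b] > 0) slots[b, seq_len(deg[b])] <- sort(nbr_list[[b]])
  }
  structure(bins,
    neighbor_slots = slots,
    adjacency = nb[nb[, 1] < nb[, 2], , drop = FALSE],
    class = c("bin_lattice", class(bins))
  )
}

#' @rdname bin_lattice
#' @param lattice A `bin_lattice`.
#' @export
n_bins <- function(lattice) nrow(lattice)

#' @rdname bin_lattice
#' @export
neighbor_slots <- function(lattice) attr(lattice, "neighbor_slots")

#' Quasi one-dimensional chain of bins
#'
#' Builds a 1 x B strip of equal-area bins with nearest-neighbour adjacency,
#' the geometry of a long narrow channel divided into quadrats (e.g. a
#' 48-bin strip for a 10 cm x 0.8 cm arena).
#'
#' @param B Number of bins.
#' @param bin_area Area of each bin (default 0.15, in cm^2).
#' @param spacing Center-to-center distance between consecutive bins.
#' @return A [bin_lattice].
#' @export
quasi1d_lattice <- function(B, bin_area = 0.15, spacing = 1) {
  stopifnot(B >= 1)
  bins <- tibble::tibble(
    bin = seq_len(B),
    x = (seq_len(B) - 1) * spacing,
    y = 0,
    area = bin_area
  )
  if (B == 1L) {
    return(bin_lattice(bins, matrix(integer(0), ncol = 2)))
  }
  nb <- cbind(seq_len(B - 1L), seq_len(B - 1L) + 1L)
  bin_lattice(bins, nb)
}

#' Rectangular grid of bins
#'
#' @param nx,ny Grid dimensions; bins are numbered row-major.
#' @param bin_area Area per bin.
#' @param spacing Center-to-center spacing along both axes.
#' @return A [bin_lattice] with 4-neighbour adjacency.
#' @export
grid_lattice <- function(nx, ny, bin_area = 0.15, spacing = 1) {
  stopifnot(nx >= 1, ny >= 1)
  idx <- function(i, j) (j - 1L) * nx + i
  bins <- tibble::tibble(
    bin = seq_len(nx * ny),
    x = rep((seq_len(nx) - 1) * spacing, times = ny),
    y = rep((seq_len(ny) - 1) * spacing, each = nx),
    area = bin_area
  )
  pairs <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (i < nx) pairs[[length(pairs) + 1L]] <- c(idx(i, j), idx(i + 1L, j))
      if (j < ny) pairs[[length(pairs) + 1L]] <- c(idx(i, j), idx(i, j + 1L))
    }
  }
  if (length(pairs) == 0) {
    return(bin_lattice(bins, matrix(integer(0), ncol = 2)))
  }
  bin_lattice(bins, do.call(rbind, pairs))
}
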