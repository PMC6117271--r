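#' Temporal autocorrelation and decorrelation time
#'
#' Normalized time autocorrelation of the bin counts,
#' \eqn{c_T(\Delta t) = \langle \sum_b N_b(t) N_b(t+\Delta t)\rangle_t /
#' \langle \sum_b N_b(t)^2 \rangle_t}, computed on per-bin mean-subtracted
#' counts so that the curve decays to 0 and its integral — the decorrelation
#' time \eqn{\tau} — is finite. \eqn{\tau} sets the down-sampling stride
#' that turns the frame sequence into effectively independent samples.
#'
#' \eqn{\tau} is the trapezoidal integral of the curve from lag 0, truncated
#' at the first non-positive value: \eqn{\tau = \Delta t \,(1/2 +
#' \sum_{k \ge 1} c_T(k))}, robust to noisy tails.
#'
#' @param counts A `count_series` tibble.
#' @param max_lag Largest lag in frames (default: half the record length).
#' @return A tibble of class `correlation_curve` with columns `lag`
#'   (seconds) and `value`; `value[lag == 0]` is 1. The decorrelation time
#'   in seconds is stored in attribute `tau` (see [decorrelation_time()]).
#' @export
temporal_autocorrelation <- function(counts, max_lag = NULL) {
  m <- counts_matrix(counts)
  n_t <- nrow(m)
  if (n_t < 2) stop("need at least 2 frames", call. = FALSE)
  dt <- frame_interval(counts)
  if (is.null(max_lag)) max_lag <- floor(n_t / 2)
  max_lag <- min(max_lag, n_t - 1L)
  centered <- sweep(m, 2, colMeans(m))
  denom <- sum(centered^2) / n_t
  if (denom <= 0) stop("degenerate input: counts are constant in time", call. = FALSE)
  vals <- vapply(0:max_lag, function(k) {
    idx <- seq_len(n_t - k)
    sum(centered[idx, , drop = FALSE] * centered[idx + k, , drop = FALSE]) /
      (n_t - k) / denom
  }, numeric(1))
  curve <- tibble::tibble(lag = (0:max_lag) * dt, value = vals)
  # integral truncated at first zero crossing of the positive-lag tail
  pos <- vals[-1]
  cross <- which(pos <= 0)
  keep <- if (length(cross)) pos[seq_len(cross[1] - 1)] else pos
  tau <- dt * (0.5 + sum(keep))
  structure(curve,
    tau = tau, normalization = "per-bin mean-subtracted",
    class = c("correlation_curve", class(curve))
  )
}

#' @rdname temporal_autocorrelation
#' @export
decorrelation_time <- function(counts) {
  if (inherits(counts, "correlation_curve")) {
    return(attr(counts, "tau"))
  }
  attr(temporal_autocorrelation(counts), "tau")
}

#' Spatial correlation between bins
#'
#' Normalized equal-time correlation between bins at displacement
#' \eqn{\Delta}: \eqn{c_S(\Delta) = \langle \sum_b N_b(t) N_{b+\Delta}(t)
#' \rangle_{b,t} / \langle N_b(t)^2 \rangle_{b,t}}, on per-bin
#' mean-subtracted counts. Independent bins give values near 0 for
#' \eqn{\Delta \ne 0} (up to the O(1/B) negative bias that the fixed total
#' agent number induces); values near 1 flag bins that fluctuate together.
#'
#' Displacements are taken along the lattice axes in units of the bin
#' spacing (bin centers are snapped to the underlying integer grid).
#'
#' @param counts A `count_series` tibble.
#' @param lattice The [bin_lattice] the columns refer to.
#' @return A `correlation_curve` tibble with columns `dx`, `dy`, `lag`
#'   (Euclidean displacement length) and `value`; `value` at `dx = dy = 0`
#'   is 1.
#' @export
spatial_correlation <- function(counts, lattice) {
  m <- counts_matrix(counts)
  B <- ncol(m)
  stopifnot(n_bins(lattice) == B)
  centered <- sweep(m, 2, colMeans(m))
  denom <- mean(colMeans(centered^2))
  if (denom <= 0) stop("degenerate input: counts are constant in time", call. = FALSE)
  gx <- snap_to_grid(lattice$x)
  gy <- snap_to_grid(lattice$y)
  cross <- crossprod(centered) / nrow(m) # B x B covariance (biased)
  pairs <- expand.grid(b1 = seq_len(B), b2 = seq_len(B))
  pairs$dx <- gx[pairs$b2] - gx[pairs$b1]
  pairs$dy <- gy[pairs$b2] - gy[pairs$b1]
  pairs$cov <- cross[cbind(pairs$b1, pairs$b2)]
  agg <- dplyr::summarise(
    dplyr::group_by(pairs, .data$dx, .data$dy),
    value = mean(.data$cov) / denom, .groups = "drop"
  )
  agg$lag <- sqrt(agg$dx^2 + agg$dy^2)
  out <- tibble::as_tibble(agg[order(agg$lag), c("dx", "dy", "lag", "value")])
  structure(out,
    normalization = "per-bin mean-subtracted",
    class = c("correlation_curve", class(out))
  )
}

# map coordinates to integer grid indices using the smallest positive spacing
snap_to_grid <- function(z) {
  u <- sort(unique(z))
  if (length(u) == 1) {
    return(rep(0L, length(z)))
  }
  h <- min(diff(u))
  as.integer(round((z - min(z)) / h))
}

#' Per-bin occupancy histograms from down-sampled frames
#'
#' Down-samples the frame sequence at the decorrelation time (stride
#' `ceil(tau / frame_interval)`, minimum 1) and tallies, for every bin, how
#' many retained frames showed each occupancy N. The retained-frame count T
#' is the effective number of independent samples and is identical across
#' bins.
#'
#' @param counts A `count_series` tibble.
#' @param tau Decorrelation time in seconds, or `NULL` to estimate it with
#'   [decorrelation_time()].
#' @param n_max Largest occupancy to tabulate (default: observed maximum).
#' @return A tibble of class `occupancy_histograms` with columns `bin`, `n`,
#'   `hits`; attribute `T` holds the number of retained frames, attribute
#'   `tau` the decorrelation time used.
#' @export
occupancy_histograms <- function(counts, tau = NULL, n_max = NULL) {
  m <- counts_matrix(counts)
  dt <- frame_interval(counts)
  if (is.null(tau)) tau <- decorrelation_time(counts)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  stride <- max(1L, as.integer(ceiling(tau / dt)))
  if (stride > nrow(m)) {
    stop("decorrelation time exceeds the record length: insufficient data", call. = FALSE)
  }
  keep <- seq(1L, nrow(m), by = stride)
  sub <- m[keep, , drop = FALSE]
  if (is.null(n_max)) n_max <- max(sub)
  T_eff <- length(keep)
  hist_one <- function(col) tabulate(factor(col, levels = 0:n_max), nbins = n_max + 1L)
  out <- tidyr::expand_grid(bin = seq_len(ncol(sub)), n = 0:n_max)
  out$hits <- as.integer(unlist(lapply(seq_len(ncol(sub)), function(b) hist_one(sub[, b]))))
  structure(out,
    T = T_eff, tau = tau, stride = stride,
    class = c("occupancy_histograms", class(out))
  )
}

#' @rdname occupancy_histograms
#' @param hist An `occupancy_histograms` tibble.
#' @export
n_samples <- function(hist) attr(hist, "T")

# hits as a B x (n_max + 1) matrix
hits_matrix <- function(hist) {
  B <- max(hist$bin)
  n_max <- max(hist$n)
  m <- matrix(0L, B, n_max + 1L)
  m[cbind(hist$bin, hist$n + 1L)] <- hist$hits
  m
}

#' Dirichlet posterior summaries of bin occupation probabilities
#'
#' Under the multivariate Haldane prior \eqn{P(\{p_N\}) \propto 1/\prod_N
#' p_N}, the posterior given hit counts \eqn{h_N} over \eqn{T} independent
#' samples is Dirichlet with parameters \eqn{h_N}. Posterior means equal
#' the observed frequencies \eqn{\bar p_N = h_N / T}, with
#' \deqn{\sigma(p_N) = \sqrt{h_N (T - h_N) / (T^2 (T+1))}, \qquad
#'   \mathrm{covar}(p_N, p_{N'}) = -h_N h_{N'} / (T^2 (T+1)).}
#' The \eqn{\sqrt{1-\bar p_N}} factor distinguishes these from naive Poisson
#' counting errors. Occupancies never observed (\eqn{h_N = 0}) get
#' \eqn{\bar p = \sigma = 0}: the Haldane prior concentrates on observed
#' categories. The variance of the mean occupation \eqn{\bar N =
#' \sum_N N p_N} follows from the same covariances.
#'
#' @param hist An `occupancy_histograms` tibble (or any tibble with `bin`,
#'   `n`, `hits` and a `T` attribute).
#' @return A tibble of class `bin_statistics` with columns `bin`, `n`,
#'   `hits`, `p_bar`, `sd`; per-bin mean occupation and its standard
#'   deviation are in attribute `mean_occupation` (a tibble with `bin`,
#'   `n_bar`, `sd`).
#' @export
dirichlet_posterior <- function(hist) {
  T_eff <- n_samples(hist)
  stopifnot(!is.null(T_eff), T_eff >= 1)
  out <- tibble::as_tibble(hist[c("bin", "n", "hits")])
  out$p_bar <- out$hits / T_eff
  out$sd <- sqrt(out$hits * (T_eff - out$hits) / (T_eff^2 * (T_eff + 1)))
  mean_occ <- dplyr::summarise(
    dplyr::group_by(out, .data$bin),
    n_bar = sum(.data$n * .data$p_bar),
    sd = sqrt(mean_occupation_variance(.data$n, .data$hits, T_eff)),
    .groups = "drop"
  )
  structure(out,
    T = T_eff, mean_occupation = mean_occ,
    class = c("bin_statistics", class(out))
  )
}

# var(N_bar) = sum_{N != N'} N N' covar + sum_N N^2 sigma^2
mean_occupation_variance <- function(n, hits, T_eff) {
  p <- hits / T_eff
  covar <- -outer(hits, hits) / (T_eff^2 * (T_eff + 1))
  diag(covar) <- hits * (T_eff - hits) / (T_eff^2 * (T_eff + 1))
  as.numeric(t(n) %*% covar %*% n)
}

#' Dirichlet posterior covariance of one bin's probabilities
#'
#' @param hist An `occupancy_histograms` tibble.
#' @param bin Bin index.
#' @return The (N_max+1) x (N_max+1) posterior covariance matrix.
#' @export
dirichlet_covariance <- function(hist, bin) {
  T_eff <- n_samples(hist)
  h <- hist$hits[hist$bin == bin][order(hist$n[hist$bin == bin])]
  covar <- -outer(h, h) / (T_eff^2 * (T_eff + 1))
  diag(covar) <- h * (T_eff - h) / (T_eff^2 * (T_eff + 1))
  covar
}

#' Pseudo-free energy of bin occupancies
#'
#' The quantity \eqn{-\ln(N! \, P_b(N)) = v_b N + \ln z_b + f_N} is linear
#' in N for a Poisson (non-interacting) bin, so any curvature isolates the
#' frustration \eqn{f_N}. Computed from observed frequencies; occupancies
#' with zero hits are omitted rather than assigned infinite values.
#' Uncertainties are propagated from the Dirichlet posterior as
#' \eqn{\sigma(p)/\bar p}.
#'
#' @param hist An `occupancy_histograms` tibble.
#' @return A tibble with columns `bin`, `n`, `value`, `sd`, one row per
#'   (bin, occupancy) cell with at least one hit.
#' @export
pseudo_free_energy <- function(hist) {
  stats <- dirichlet_posterior(hist)
  keep <- stats$hits > 0
  if (!any(keep)) stop("empty histogram", call. = FALSE)
  out <- tibble::as_tibble(stats[keep, c("bin", "n")])
  p <- stats$p_bar[keep]
  out$value <- -(lfactorial(out$n) + log(p))
  out$sd <- stats$sd[keep] / p
  out
}

#' Collapse pseudo-free energies onto a single frustration
#'
#' Removes the fitted per-bin Poisson contribution \eqn{v_b N + \ln z_b}
#' from each bin's pseudo-free energy and compares the remainder with the
#' model frustration \eqn{f_N}. If a single universal frustration describes
#' every bin, the residuals scatter around 0 with unit standardized spread.
#'
#' @param hist An `occupancy_histograms` tibble.
#' @param model A fitted [dfft_model] supplying `v`, `mu` and `f`.
#' @return A tibble with columns `bin`, `n`, `collapsed` (pseudo-free
#'   energy minus the Poisson part), `f` (model frustration), `residual`,
#'   `sd`; attribute `score` holds the hit-weighted RMS standardized
#'   residual (chi-like: ~1 when the collapse holds).
#' @export
collapse_curves <- function(hist, model) {
  pfe <- pseudo_free_energy(hist)
  lz <- log_partition(model)
  pfe$collapsed <- pfe$value - ((model$v[pfe$bin] - model$mu) * pfe$n + lz[pfe$bin])
  pfe$f <- model$f[pfe$n + 1L]
  pfe$residual <- pfe$collapsed - pfe$f
  score <- sqrt(mean((pfe$residual / pfe$sd)^2))
  out <- pfe[, c("bin", "n", "collapsed", "f", "residual", "sd")]
  structure(out, score = score, class = c("collapse_table", class(out)))
}

#' @rdname collapse_curves
#' @param x A `collapse_table`.
#' @export
collapse_score <- function(x) attr(x, "score")
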