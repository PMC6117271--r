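#' Solve the chemical potential for a target population
#'
#' In the grand-canonical picture the bins are independent with occupancy
#' law \eqn{P_b(N) \propto e^{-(v_b - \mu)N - f_N}/N!}; the total mean
#' occupation \eqn{\sum_b \bar N_b(\mu)} is strictly increasing in
#' \eqn{\mu}, so a unique \eqn{\mu} pins the crowd size at `n_tot`. Found
#' by bracketed root finding with automatic bracket expansion.
#'
#' @param model A [dfft_model] (its `mu` field is ignored).
#' @param n_tot Target total number of agents; must be positive and below
#'   the hard capacity `B * n_max`.
#' @param tol Relative tolerance on the total occupation (default 1e-10).
#' @return The chemical potential (a single number).
#' @export
solve_mu <- function(model, n_tot, tol = 1e-10) {
  B <- length(model$v)
  if (n_tot <= 0) stop("n_tot must be positive", call. = FALSE)
  if (n_tot >= B * model$n_max) {
    stop("n_tot infeasible under the N_max packing cap", call. = FALSE)
  }
  total <- function(mu) {
    m <- model
    m$mu <- mu
    sum(prob_matrix(m) %*% (0:model$n_max))
  }
  lo <- -1
  hi <- 1
  while (total(lo) > n_tot && lo > -745) lo <- lo * 2
  while (total(hi) < n_tot && hi < 745) hi <- hi * 2
  root <- stats::uniroot(function(mu) total(mu) - n_tot,
    lower = lo, upper = hi,
    tol = .Machine$double.eps^0.75
  )$root
  # polish: Newton steps on the monotone map (derivative = total variance)
  for (i in 1:50) {
    m <- model
    m$mu <- root
    P <- prob_matrix(m)
    N <- 0:model$n_max
    tot <- sum(P %*% N)
    if (abs(tot - n_tot) <= tol * n_tot) break
    slope <- sum(P %*% N^2) - sum((P %*% N)^2)
    root <- root + (n_tot - tot) / slope
  }
  root
}

as_dfft_parts <- function(x) {
  if (inherits(x, "dfft_fit")) x$model else x
}

#' Predict crowd density in a new setting
#'
#' The mix-and-match protocol: take a vexation measured in the target arena
#' (typically from a sparse, vexation-only fit where interactions are
#' invisible) and a frustration measured in a reference experiment
#' (interactions are a property of the agents, not the arena), solve the
#' chemical potential so that the predicted means sum to the new population
#' size, and report per-bin mean occupations with linearized uncertainties.
#'
#' Uncertainty propagation uses
#' \eqn{\partial \bar N_b / \partial v_b = -(\langle N^2\rangle_b - \bar
#' N_b^2)} and \eqn{\partial \bar N_b / \partial f_N = -(N - \bar N_b)
#' P_b(N)}, with frustration sums running from N = 2 (the gauge makes
#' \eqn{f_0, f_1} exact). Vexation and frustration covariances are taken
#' from the two (independent) source experiments; their cross-covariance is
#' zero.
#'
#' @param vexation_from A `dfft_fit` for the target arena (or a
#'   [dfft_model]); supplies \eqn{v_b} and, if a fit, `var(v_b)`.
#' @param frustration_from A `dfft_fit` for the reference experiment (or a
#'   [dfft_model]); supplies \eqn{f_N} and, if a fit, `covar(f_N, f_N')`.
#' @param n_tot Number of agents to place in the target arena.
#' @return A tibble of class `dfft_prediction` with columns `bin`, `n_bar`,
#'   `sd`; attributes `mu` (solved chemical potential) and `model` (the
#'   combined [dfft_model] at that `mu`, for per-bin distributions via
#'   [bin_probabilities()]).
#' @export
predict_density <- function(vexation_from, frustration_from, n_tot) {
  vm <- as_dfft_parts(vexation_from)
  fm <- as_dfft_parts(frustration_from)
  base <- dfft_model(vm$v, fm$f, mu = 0)
  mu <- solve_mu(base, n_tot)
  model <- dfft_model(vm$v, fm$f, mu = mu)

  v_var <- if (inherits(vexation_from, "dfft_fit")) {
    diag(cov_block(vexation_from, "v"))
  } else {
    rep(0, length(vm$v))
  }
  f_cov <- if (inherits(frustration_from, "dfft_fit") && frustration_from$interactions) {
    cov_block(frustration_from, "f")
  } else {
    matrix(0, max(fm$n_max - 1L, 0L), max(fm$n_max - 1L, 0L))
  }
  sd <- prediction_uncertainty(model, v_var, f_cov)
  P <- prob_matrix(model)
  out <- tibble::tibble(
    bin = seq_along(vm$v),
    n_bar = as.numeric(P %*% (0:model$n_max)),
    sd = sd
  )
  structure(out,
    mu = mu, model = model,
    class = c("dfft_prediction", class(out))
  )
}

#' Linearized uncertainty of predicted mean occupations
#'
#' @param model The combined [dfft_model] at the solved chemical potential.
#' @param v_var Per-bin variance of the vexation estimates (length B).
#' @param f_cov Covariance matrix of the free frustrations `f_2..f_Nmax`.
#' @return Numeric vector of per-bin standard deviations.
#' @export
prediction_uncertainty <- function(model, v_var, f_cov) {
  B <- length(model$v)
  stopifnot(length(v_var) == B)
  n_free <- model$n_max - 1L
  if (!all(dim(f_cov) == c(n_free, n_free))) {
    stop("f_cov must cover f_2..f_Nmax", call. = FALSE)
  }
  P <- prob_matrix(model)
  N <- 0:model$n_max
  nbar <- as.numeric(P %*% N)
  varN <- as.numeric(P %*% N^2) - nbar^2
  vapply(seq_len(B), function(b) {
    d_v <- -varN[b]
    var_b <- d_v^2 * v_var[b]
    if (n_free > 0) {
      d_f <- -(N - nbar[b]) * P[b, ] # full 0..n_max, then drop f_0, f_1
      d_f <- d_f[-(1:2)]
      var_b <- var_b + as.numeric(t(d_f) %*% f_cov %*% d_f)
    }
    sqrt(max(var_b, 0))
  }, numeric(1))
}

#' Compare predicted and observed density distributions
#'
#' @param predicted A `dfft_prediction` (columns `bin`, `n_bar`, `sd`).
#' @param observed A data frame with columns `bin`, `n_bar`, `sd` — e.g.
#'   the `mean_occupation` attribute of [dirichlet_posterior()] applied to
#'   the dense-experiment histograms.
#' @return A tibble of class `comparison_report` with one row per bin
#'   (`bin`, `predicted`, `observed`, `residual`, `standardized`);
#'   attributes `r` (Pearson correlation of the per-bin means) and
#'   `sigma_mean` (mean absolute standardized residual,
#'   \eqn{|\Delta|/\sqrt{\sigma_{pred}^2 + \sigma_{obs}^2}}; ~1 when the
#'   prediction matches within the stated uncertainties).
#' @export
compare_distributions <- function(predicted, observed) {
  stopifnot(all(c("bin", "n_bar") %in% names(observed)))
  if (nrow(predicted) < 3) stop("need at least 3 bins to compare", call. = FALSE)
  obs <- observed[match(predicted$bin, observed$bin), ]
  sd_obs <- if ("sd" %in% names(obs)) obs$sd else 0
  pooled <- sqrt(predicted$sd^2 + sd_obs^2)
  resid <- predicted$n_bar - obs$n_bar
  std <- ifelse(pooled > 0, abs(resid) / pooled, ifelse(resid == 0, 0, Inf))
  out <- tibble::tibble(
    bin = predicted$bin,
    predicted = predicted$n_bar,
    observed = obs$n_bar,
    residual = resid,
    standardized = std
  )
  r <- if (stats::sd(predicted$n_bar) == 0 || stats::sd(obs$n_bar) == 0) {
    NA_real_
  } else {
    stats::cor(predicted$n_bar, obs$n_bar)
  }
  structure(out,
    r = r, sigma_mean = mean(std),
    class = c("comparison_report", class(out))
  )
}

#' Glance at a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return A one-row tibble with `r`, `sigma_mean`, `n_bins`.
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    r = attr(x, "r"), sigma_mean = attr(x, "sigma_mean"), n_bins = nrow(x)
  )
}
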