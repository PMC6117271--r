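#' Negative log-posterior of a DFFT model
#'
#' The (per-bin independent) likelihood of down-sampled histograms under the
#' modified Poisson law, plus a Gaussian prior of scale `prior_sigma` on
#' every vexation and frustration parameter:
#' \deqn{-\ln P = \sum_b \Big( T \ln z_b + \sum_N h_{bN} (v_b N + f_N +
#'   \ln N!) \Big) + \sum_N \frac{f_N^2}{2\sigma^2} + \sum_b
#'   \frac{v_b^2}{2\sigma^2}}
#' (dropping the parameter-independent normalization constant). The
#' chemical potential is fixed at 0 during fitting; it is re-solved only at
#' prediction time. The likelihood part is the log-partition function of an
#' exponential family, so the objective is convex in (f, v).
#'
#' @param model A [dfft_model] whose `n_max` covers every observed
#'   occupancy.
#' @param hist An `occupancy_histograms` tibble.
#' @param prior_sigma Gaussian prior scale (default 15; the parameters
#'   enter as exponentials so magnitudes beyond ~15 are implausible).
#' @return A single number.
#' @export
neg_log_posterior <- function(model, hist, prior_sigma = 15) {
  H <- hits_matrix(hist)
  T_eff <- n_samples(hist)
  if (ncol(H) - 1L > model$n_max) {
    stop("observed occupancy exceeds the model's N_max", call. = FALSE)
  }
  if (ncol(H) - 1L < model$n_max) {
    H <- cbind(H, matrix(0L, nrow(H), model$n_max + 1L - ncol(H)))
  }
  nlp_objective(
    pack_params(model$f, model$v), B = length(model$v), n_max = model$n_max,
    H = H, T_eff = T_eff, prior_sigma = prior_sigma
  )
}

# free parameter vector: (f_2 .. f_nmax, v_1 .. v_B); f_0 = f_1 = 0 hard-coded
pack_params <- function(f, v) c(f[-(1:2)], v)

unpack_params <- function(theta, B, n_max) {
  n_f <- n_max - 1L
  list(f = c(0, 0, theta[seq_len(n_f)]), v = theta[n_f + seq_len(B)])
}

# objective and gradient on the packed parameter vector (mu = 0)
nlp_objective <- function(theta, B, n_max, H, T_eff, prior_sigma) {
  par <- unpack_params(theta, B, n_max)
  N <- 0:n_max
  lfac <- lfactorial(N)
  val <- 0
  for (b in seq_len(B)) {
    lw <- -par$v[b] * N - par$f - lfac
    m <- max(lw)
    lz <- m + log(sum(exp(lw - m)))
    val <- val + T_eff * lz + sum(H[b, ] * (par$v[b] * N + par$f + lfac))
  }
  val + sum(par$f^2) / (2 * prior_sigma^2) + sum(par$v^2) / (2 * prior_sigma^2)
}

nlp_gradient <- function(theta, B, n_max, H, T_eff, prior_sigma) {
  par <- unpack_params(theta, B, n_max)
  N <- 0:n_max
  lfac <- lfactorial(N)
  g_f <- numeric(n_max + 1L)
  g_v <- numeric(B)
  for (b in seq_len(B)) {
    lw <- -par$v[b] * N - par$f - lfac
    p <- exp(lw - max(lw))
    p <- p / sum(p)
    g_v[b] <- sum(H[b, ] * N) - T_eff * sum(N * p) + par$v[b] / prior_sigma^2
    g_f <- g_f + (H[b, ] - T_eff * p)
  }
  g_f <- g_f + par$f / prior_sigma^2
  c(g_f[-(1:2)], g_v)
}

#' Fit a DFFT model to occupancy histograms
#'
#' Maximum a posteriori estimation of the vexation \eqn{v_b} and
#' frustration \eqn{f_N} from bin-count fluctuations, by gradient-based
#' minimization of [neg_log_posterior()]. The gauge is fixed by excluding
#' \eqn{f_0} and \eqn{f_1} from the free parameters; the chemical potential
#' is 0 by convention. The objective is convex, so the optimum is unique.
#'
#' @param x A `count_series` tibble (histograms are built with
#'   [occupancy_histograms()] at the estimated decorrelation time) or an
#'   `occupancy_histograms` tibble.
#' @param prior_sigma Gaussian prior scale on all parameters (default 15).
#' @param n_max Maximum occupancy to model. Default: the largest observed
#'   occupancy plus 3 (frustration is unidentifiable beyond observed
#'   occupancies, and the prior keeps the extra values tame).
#' @param tau Decorrelation time in seconds when `x` is a count series
#'   (`NULL`: estimated from the data).
#' @param interactions If `FALSE`, fit the vexation-only (Poisson) model
#'   with the frustration frozen at zero — appropriate for very sparse data
#'   where interactions are unidentifiable (see [fit_poisson()]).
#' @param gradient_tolerance Convergence criterion on the gradient max-norm.
#' @param max_iterations Iteration cap passed to the optimizer.
#' @return An object of class `dfft_fit`: a list with `model` (the MAP
#'   [dfft_model]), `covariance` (free-parameter covariance, rows/columns
#'   named `f_2..f_Nmax, v_1..v_B`), `objective`, `log_lik` (likelihood
#'   part at the MAP, for model comparison), `T`, `prior_sigma`,
#'   `converged`, `hist` (the histograms used). Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_dfft <- function(x, prior_sigma = 15, n_max = NULL, tau = NULL,
                     interactions = TRUE,
                     gradient_tolerance = 1e-5, max_iterations = 1000) {
  hist <- if (inherits(x, "occupancy_histograms")) x else occupancy_histograms(x, tau = tau)
  H <- hits_matrix(hist)
  T_eff <- n_samples(hist)
  obs_max <- max(hist$n[hist$hits > 0])
  if (is.null(n_max)) n_max <- obs_max + 3L
  if (n_max < obs_max) stop("n_max below the largest observed occupancy", call. = FALSE)
  if (ncol(H) - 1L < n_max) H <- cbind(H, matrix(0L, nrow(H), n_max + 1L - ncol(H)))
  B <- nrow(H)
  N <- 0:n_max

  if (all(apply(H, 1, function(h) sum(h > 0)) == 1L)) {
    stop("degenerate data: every frame is identical", call. = FALSE)
  }

  if (interactions) {
    theta0 <- c(
      numeric(n_max - 1L),
      -log(pmax(as.numeric(H %*% N) / T_eff, 0.5 / T_eff)) # Poisson start
    )
    opt <- stats::optim(
      theta0, nlp_objective, nlp_gradient,
      B = B, n_max = n_max, H = H, T_eff = T_eff, prior_sigma = prior_sigma,
      method = "BFGS",
      control = list(maxit = max_iterations, reltol = 1e-14)
    )
    theta <- opt$par
    par <- unpack_params(theta, B, n_max)
  } else {
    # vexation-only: per-bin convex 1-D problems
    v <- vapply(seq_len(B), function(b) {
      stats::optimize(function(vb) {
        lw <- -vb * N - lfactorial(N)
        m <- max(lw)
        T_eff * (m + log(sum(exp(lw - m)))) + vb * sum(H[b, ] * N) +
          vb^2 / (2 * prior_sigma^2)
      }, interval = c(-3 * prior_sigma, 3 * prior_sigma), tol = 1e-12)$minimum
    }, numeric(1))
    par <- list(f = numeric(n_max + 1L), v = v)
    theta <- pack_params(par$f, par$v)
    opt <- list(
      value = nlp_objective(theta, B, n_max, H, T_eff, prior_sigma),
      counts = NA
    )
  }

  grad <- nlp_gradient(theta, B, n_max, H, T_eff, prior_sigma)
  free_grad <- if (interactions) grad else grad[n_max - 1L + seq_len(B)]
  converged <- max(abs(free_grad)) <= gradient_tolerance * max(1, T_eff)
  model <- dfft_model(par$v, par$f, mu = 0)
  log_lik <- -(opt$value - sum(par$f^2) / (2 * prior_sigma^2) -
    sum(par$v^2) / (2 * prior_sigma^2))

  fit <- structure(
    list(
      model = model, objective = opt$value, log_lik = log_lik,
      T = T_eff, prior_sigma = prior_sigma, interactions = interactions,
      converged = converged, hist = hist
    ),
    class = "dfft_fit"
  )
  fit$covariance <- parameter_covariance(fit)
  fit
}

#' @rdname fit_dfft
#' @param ... Passed on to [fit_dfft()].
#' @export
fit_poisson <- function(x, ...) fit_dfft(x, interactions = FALSE, ...)

#' Fisher information matrix of the DFFT likelihood
#'
#' Expected information of the histogram likelihood at a model, i.e. the
#' exact Hessian of the negative log-likelihood (no prior), laid out in
#' blocks over \eqn{(f_0 \ldots f_{N_{max}}, v_1 \ldots v_B)}:
#' \deqn{[I_{ff}]_{N N'} = T \sum_b (\delta_{NN'} P_b(N) - P_b(N) P_b(N')),}
#' \deqn{[I_{fv}]_{N b} = T P_b(N) (N - \bar N_b), \qquad
#'   [I_{vv}]_{b b'} = T \delta_{bb'} \mathrm{Var}_b(N).}
#' Before gauge fixing the matrix is singular: the two gauge directions
#' (pure \eqn{\beta}: f-part all ones; \eqn{\alpha}: f-part \eqn{N}, v-part
#' \eqn{-1}) are annihilated. `gauge_fixed = TRUE` drops the \eqn{f_0},
#' \eqn{f_1} rows and columns, which removes the singularity.
#'
#' @param model A [dfft_model].
#' @param T_eff Number of independent samples the information refers to.
#' @param gauge_fixed Drop the first two frustration rows/columns (default
#'   `TRUE`).
#' @return A square matrix with dimnames `f_0..f_Nmax, v_1..v_B` (or
#'   `f_2..` when gauge-fixed).
#' @export
fisher_information <- function(model, T_eff, gauge_fixed = TRUE) {
  P <- prob_matrix(model) # B x (n_max + 1)
  B <- nrow(P)
  N <- 0:model$n_max
  nbar <- as.numeric(P %*% N)
  varN <- as.numeric(P %*% N^2) - nbar^2
  I_ff <- T_eff * (diag(colSums(P), model$n_max + 1L) - crossprod(P))
  I_fv <- T_eff * t(P) * outer(N, nbar, "-") # [N, b] = T P_b(N) (N - Nbar_b)
  I_vv <- diag(T_eff * varN, B)
  I <- rbind(
    cbind(I_ff, I_fv),
    cbind(t(I_fv), I_vv)
  )
  dimnames(I) <- rep(list(c(paste0("f_", N), paste0("v_", seq_len(B)))), 2)
  if (gauge_fixed) I <- I[-(1:2), -(1:2), drop = FALSE]
  I
}

#' Parameter covariance of a fitted model
#'
#' Inverse of the gauge-fixed Fisher information at the MAP (the asymptotic
#' Gaussian covariance of the free parameters `f_2..f_Nmax, v_1..v_B`).
#' When the likelihood information is singular — e.g. occupancies never
#' observed — the prior curvature \eqn{1/\sigma^2} is added to the diagonal
#' as a regularization fallback, and if that still fails a pseudo-inverse
#' is used, with a warning in both cases.
#'
#' @param fit A `dfft_fit`.
#' @return A symmetric positive (semi)definite matrix with the same
#'   dimnames as the gauge-fixed Fisher matrix; for vexation-only fits,
#'   only the `v` block.
#' @export
parameter_covariance <- function(fit) {
  I <- fisher_information(fit$model, fit$T, gauge_fixed = TRUE)
  if (!fit$interactions) {
    vn <- grep("^v_", rownames(I))
    I <- I[vn, vn, drop = FALSE]
  }
  cov <- tryCatch(chol2inv(chol(I)), error = function(e) NULL)
  if (is.null(cov)) {
    warning("likelihood Fisher information is singular; adding prior curvature",
      call. = FALSE
    )
    I2 <- I + diag(1 / fit$prior_sigma^2, nrow(I))
    cov <- tryCatch(chol2inv(chol(I2)), error = function(e) NULL)
    if (is.null(cov)) {
      warning("using pseudo-inverse for parameter covariance", call. = FALSE)
      cov <- pseudo_inverse(I2)
    }
  }
  dimnames(cov) <- dimnames(I)
  cov
}

pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# covariance sub-blocks by parameter name
cov_block <- function(fit, what = c("f", "v")) {
  what <- match.arg(what)
  idx <- grep(paste0("^", what, "_"), rownames(fit$covariance))
  fit$covariance[idx, idx, drop = FALSE]
}

#' Compare the DFFT fit against the vexation-only fit
#'
#' Two diagnostics of whether the frustration is warranted by the data:
#' a reduced chi-squared per model, computed over (bin, occupancy) cells as
#' \eqn{(h_{bN} - T P_b(N))^2 / (T P_b(N) (1 - P_b(N)))} with consecutive
#' occupancy cells pooled within each bin until every cell has expected
#' hits of at least 5, and a likelihood-ratio test of the nested
#' vexation-only model (statistic \eqn{2 \Delta \log L}, degrees of freedom
#' = number of free frustration values, p-value from the chi-squared tail).
#'
#' @param fit_dfft,fit_poisson Fits of the full and vexation-only models on
#'   the same histograms.
#' @param hist The shared `occupancy_histograms` (default: taken from
#'   `fit_dfft`).
#' @return A tibble with one row per model: columns `model`, `chisq`,
#'   `n_cells`, `n_free`, `dof`, `chisq_reduced`; attributes `lrt_stat`,
#'   `lrt_dof`, `lrt_p`.
#' @export
model_comparison <- function(fit_dfft, fit_poisson, hist = fit_dfft$hist) {
  stopifnot(identical(n_samples(hist), fit_dfft$T), identical(fit_dfft$T, fit_poisson$T))
  row <- function(fit, label, n_free) {
    gof <- pooled_chisq(fit$model, hist)
    dof <- gof$n_cells - n_free
    if (dof <= 0) stop("non-positive degrees of freedom after pooling", call. = FALSE)
    tibble::tibble(
      model = label, chisq = gof$chisq, n_cells = gof$n_cells,
      n_free = n_free, dof = dof, chisq_reduced = gof$chisq / dof
    )
  }
  B <- length(fit_dfft$model$v)
  n_free_f <- fit_dfft$model$n_max - 1L
  out <- dplyr::bind_rows(
    row(fit_dfft, "dfft", n_free_f + B),
    row(fit_poisson, "poisson", B)
  )
  lrt <- 2 * (fit_dfft$log_lik - fit_poisson$log_lik)
  structure(out,
    lrt_stat = lrt, lrt_dof = n_free_f,
    lrt_p = stats::pchisq(lrt, df = n_free_f, lower.tail = FALSE),
    class = c("model_comparison", class(out))
  )
}

# chi-squared over (bin, occupancy) cells, pooling consecutive occupancies
# within a bin until each pooled cell has expected hits >= 5
pooled_chisq <- function(model, hist, min_expected = 5) {
  H <- hits_matrix(hist)
  T_eff <- n_samples(hist)
  if (ncol(H) - 1L < model$n_max) {
    H <- cbind(H, matrix(0L, nrow(H), model$n_max + 1L - ncol(H)))
  }
  P <- prob_matrix(model)
  chisq <- 0
  n_cells <- 0L
  for (b in seq_len(nrow(H))) {
    groups <- pool_cells(T_eff * P[b, ], min_expected)
    for (g in groups) {
      p <- sum(P[b, g])
      h <- sum(H[b, g])
      e <- T_eff * p
      if (e <= 0 || p >= 1) next
      chisq <- chisq + (h - e)^2 / (e * (1 - p))
      n_cells <- n_cells + 1L
    }
  }
  list(chisq = chisq, n_cells = n_cells)
}

# greedy left-to-right pooling; a trailing short group is merged backwards
pool_cells <- function(expected, min_expected) {
  groups <- list()
  current <- integer(0)
  for (i in seq_along(expected)) {
    current <- c(current, i)
    if (sum(expected[current]) >= min_expected) {
      groups[[length(groups) + 1L]] <- current
      current <- integer(0)
    }
  }
  if (length(current)) {
    if (length(groups)) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], current)
    } else {
      groups[[1L]] <- current
    }
  }
  groups
}

#' Prior-sensitivity diagnostic
#'
#' Refits with a deliberately tight prior and reports the relative change
#' of the frustration values — a check that the data, not the prior, drive
#' the estimate.
#'
#' @param fit A `dfft_fit`.
#' @param tight_sigma Alternative prior scale (default 1).
#' @return A tibble with `sigma`, `relative_change` (L2 change of the free
#'   frustrations relative to their L2 norm).
#' @export
prior_sensitivity <- function(fit, tight_sigma = 1) {
  refit <- fit_dfft(fit$hist,
    prior_sigma = tight_sigma,
    n_max = fit$model$n_max, interactions = fit$interactions
  )
  f0 <- fit$model$f[-(1:2)]
  f1 <- refit$model$f[-(1:2)]
  tibble::tibble(
    sigma = tight_sigma,
    relative_change = sqrt(sum((f1 - f0)^2)) / max(sqrt(sum(f0^2)), .Machine$double.eps)
  )
}

#' @export
print.dfft_fit <- function(x, ...) {
  cat(
    "<dfft_fit>", if (x$interactions) "DFFT (vexation + frustration)" else "vexation-only (Poisson)",
    "\n  B =", length(x$model$v), " N_max =", x$model$n_max, " T =", x$T,
    "\n  objective =", format(x$objective), " converged =", x$converged, "\n"
  )
  invisible(x)
}

#' Tidy a DFFT fit
#'
#' @param x A `dfft_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term` (`f_2..`,
#'   `v_1..`), `estimate`, `std.error`.
#' @method tidy dfft_fit
#' @export
tidy.dfft_fit <- function(x, ...) {
  terms <- rownames(x$covariance)
  est <- c(
    if (x$interactions) x$model$f[-(1:2)] else numeric(0),
    x$model$v
  )
  tibble::tibble(
    term = terms, estimate = est,
    std.error = sqrt(pmax(diag(x$covariance), 0))
  )
}

#' Glance at a DFFT fit
#'
#' @inheritParams tidy.dfft_fit
#' @return A one-row tibble with `objective`, `log_lik`, `T`, `B`, `n_max`,
#'   `prior_sigma`, `converged`.
#' @method glance dfft_fit
#' @export
glance.dfft_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, log_lik = x$log_lik, T = x$T,
    B = length(x$model$v), n_max = x$model$n_max,
    prior_sigma = x$prior_sigma, converged = x$converged
  )
}
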