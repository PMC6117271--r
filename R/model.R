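#' DFFT crowd models
#'
#' A DFFT model describes the stationary statistics of a crowd through two
#' functions: a per-bin vexation \eqn{v_b} (intrinsic dissatisfaction with a
#' location; lower values attract agents) and an occupancy-dependent
#' frustration \eqn{f_N} (dissatisfaction of a bin holding \eqn{N} agents;
#' positive curvature means repulsion, negative attraction). Together with a
#' chemical potential \eqn{\mu} they define per-bin occupancy distributions
#' \deqn{P_b(N) = z_b^{-1} \frac{1}{N!} e^{-(v_b-\mu)N} e^{-f_N},}
#' a modified Poisson law that reduces to Poisson when \eqn{f \equiv 0}.
#'
#' The exponent \eqn{\ln z_b + (v_b-\mu)N + f_N} is invariant under the gauge
#' transformation \eqn{v_b \to v_b - \alpha}, \eqn{f_N \to f_N + \beta +
#' \alpha N}; the ambiguity is resolved by the convention \eqn{f_0 = f_1 = 0},
#' which the constructor enforces.
#'
#' @param vexation Numeric vector of per-bin vexations (length B).
#' @param frustration Numeric vector \eqn{(f_0, f_1, \ldots, f_{N_{max}})};
#'   must have `frustration[1] == 0` and `frustration[2] == 0`.
#' @param mu Chemical potential (default 0, the convention used during
#'   inference; re-solved at prediction time for new population sizes).
#' @return An object of class `dfft_model` with fields `v`, `f`, `mu`,
#'   `n_max`.
#' @examples
#' m <- dfft_model(vexation = c(0, 1), frustration = c(0, 0, 0.5))
#' bin_probabilities(m)
#' @export
dfft_model <- function(vexation, frustration, mu = 0) {
  v <- as.numeric(vexation)
  f <- as.numeric(frustration)
  if (length(f) < 2) stop("frustration needs at least f_0 and f_1", call. = FALSE)
  if (!all(is.finite(v)) || !all(is.finite(f)) || !is.finite(mu)) {
    stop("model parameters must all be finite", call. = FALSE)
  }
  tol <- 1e-9
  if (abs(f[1]) > tol || abs(f[2]) > tol) {
    stop("gauge violation: the model convention requires f_0 = f_1 = 0 ",
      "(use refix_gauge() to re-gauge)",
      call. = FALSE
    )
  }
  f[1:2] <- 0
  structure(
    list(v = v, f = f, mu = as.numeric(mu), n_max = length(f) - 1L),
    class = "dfft_model"
  )
}

#' @export
print.dfft_model <- function(x, ...) {
  cat(
    "<dfft_model> B =", length(x$v), "bins, N_max =", x$n_max,
    ", mu =", format(x$mu), "\n"
  )
  cat("  vexation range: [", format(min(x$v)), ",", format(max(x$v)), "]\n")
  cat("  frustration:", paste(format(x$f, digits = 3), collapse = " "), "\n")
  invisible(x)
}

# log unnormalized weight of occupancy N in bin b: -(v_b - mu) N - f_N - ln N!
log_bin_weights <- function(model, bin) {
  N <- 0:model$n_max
  -(model$v[bin] - model$mu) * N - model$f - lfactorial(N)
}

#' Per-bin occupancy probabilities
#'
#' Evaluates the modified Poisson distribution \eqn{P_b(N)} for each
#' requested bin, computed in log space with a subtract-max normalization so
#' that vexations and frustrations of magnitude up to ~15 are safe.
#'
#' @param model A [dfft_model].
#' @param bins Integer vector of bin indices (default: all bins).
#' @return A tibble with columns `bin`, `n` (0..N_max) and `prob`; for each
#'   bin the probabilities sum to 1.
#' @export
bin_probabilities <- function(model, bins = seq_along(model$v)) {
  stopifnot(inherits(model, "dfft_model"), all(bins >= 1), all(bins <= length(model$v)))
  rows <- lapply(bins, function(b) {
    lw <- log_bin_weights(model, b)
    p <- exp(lw - max(lw))
    tibble::tibble(bin = b, n = 0:model$n_max, prob = p / sum(p))
  })
  dplyr::bind_rows(rows)
}

# B x (N_max + 1) matrix of P_b(N); the internal workhorse
prob_matrix <- function(model) {
  B <- length(model$v)
  out <- matrix(0, B, model$n_max + 1L)
  for (b in seq_len(B)) {
    lw <- log_bin_weights(model, b)
    p <- exp(lw - max(lw))
    out[b, ] <- p / sum(p)
  }
  out
}

# per-bin log z_b with mu folded in (z_b = sum_N e^{-(v_b-mu)N - f_N}/N!)
log_partition <- function(model) {
  vapply(seq_along(model$v), function(b) {
    lw <- log_bin_weights(model, b)
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }, numeric(1))
}

#' Discretized crowd Hamiltonian
#'
#' Global dissatisfaction of an occupancy configuration:
#' \eqn{H = \sum_b (f_{N_b} + v_b N_b)}.
#'
#' @param model A [dfft_model].
#' @param occupancy Integer vector of per-bin counts (length B, each within
#'   0..N_max).
#' @return A single number.
#' @export
hamiltonian <- function(model, occupancy) {
  stopifnot(length(occupancy) == length(model$v))
  if (any(occupancy < 0)) stop("occupancies must be nonnegative", call. = FALSE)
  if (any(occupancy > model$n_max)) {
    stop("occupancy exceeds the model's N_max", call. = FALSE)
  }
  sum(model$f[occupancy + 1L]) + sum(model$v * occupancy)
}

#' Dissatisfaction change of a single-agent move
#'
#' Exact change of the Hamiltonian when one agent moves between bins:
#' \eqn{\Delta H = (v_{to} - v_{from}) + (f_{N_{to}+1} - f_{N_{to}}) +
#' (f_{N_{from}-1} - f_{N_{from}})}, i.e. the forward difference of f at the
#' destination plus the reverse difference at the origin.
#'
#' @inheritParams hamiltonian
#' @param from,to Bin indices; `occupancy[from]` must be at least 1 and
#'   `occupancy[to]` below N_max.
#' @export
delta_H <- function(model, occupancy, from, to) {
  if (occupancy[from] < 1) stop("cannot move an agent out of an empty bin", call. = FALSE)
  if (occupancy[to] >= model$n_max) {
    stop("destination bin is at the packing limit N_max", call. = FALSE)
  }
  f <- model$f
  Nt <- occupancy[to]
  Nf <- occupancy[from]
  (model$v[to] - model$v[from]) +
    (f[Nt + 2L] - f[Nt + 1L]) +
    (f[Nf] - f[Nf + 1L])
}

#' Gauge transformation of a model
#'
#' Applies \eqn{v_b \to v_b - \alpha}, \eqn{f_N \to f_N + \beta + \alpha N},
#' which leaves every bin distribution unchanged. The result generally
#' violates the `f_0 = f_1 = 0` convention, so it is returned as a plain
#' list with the same fields; [refix_gauge()] restores the convention.
#'
#' @param model A [dfft_model] (or the list returned by a previous
#'   transform).
#' @param alpha,beta Gauge parameters.
#' @return A model-shaped list with fields `v`, `f`, `mu`, `n_max`.
#' @export
gauge_transform <- function(model, alpha, beta) {
  N <- 0:model$n_max
  out <- list(
    v = model$v - alpha,
    f = model$f + beta + alpha * N,
    mu = model$mu,
    n_max = model$n_max
  )
  class(out) <- "dfft_model_ungauged"
  out
}

#' Restore the f_0 = f_1 = 0 gauge
#'
#' Solves for the unique \eqn{(\alpha, \beta)} that zeroes \eqn{f_0} and
#' \eqn{f_1} and returns a proper [dfft_model]. Predictions are unchanged.
#'
#' @param model A model or ungauged model list.
#' @export
refix_gauge <- function(model) {
  # f_N + beta + alpha N = 0 at N = 0, 1  =>  beta = -f_0, alpha = -(f_1 - f_0)
  beta <- -model$f[1]
  alpha <- -(model$f[2] - model$f[1])
  N <- 0:model$n_max
  dfft_model(
    vexation = model$v - alpha,
    frustration = model$f + beta + alpha * N,
    mu = model$mu
  )
}

#' Unnormalized log-weight of a closed-system configuration
#'
#' The joint stationary law of a closed crowd of \eqn{N_{tot}} agents is
#' \deqn{P(\{N_b\}) = \frac{N_{tot}!}{Z} \prod_b
#'   \frac{e^{-f_{N_b} - v_b N_b}}{N_b!}.}
#' This returns the log of the unnormalized weight (including the
#' \eqn{N_{tot}!} factor); normalization over all configurations with the
#' same total is the caller's job (see [enumerate_stationary()]).
#'
#' @inheritParams hamiltonian
#' @export
log_joint_weight <- function(model, occupancy) {
  if (any(occupancy > model$n_max)) {
    stop("occupancy exceeds the model's N_max", call. = FALSE)
  }
  lfactorial(sum(occupancy)) - hamiltonian(model, occupancy) -
    sum(lfactorial(occupancy))
}

#' @rdname log_joint_weight
#' @export
joint_probability <- function(model, occupancy) exp(log_joint_weight(model, occupancy))
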