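#' Barker acceptance probability
#'
#' Probability that an agent executes a contemplated move with
#' dissatisfaction change `delta_h`: \eqn{1/(e^{\Delta H} + 1)}.
#' Monotonically decreasing, exactly 0.5 at \eqn{\Delta H = 0}; moves that
#' lower dissatisfaction are likely, moves that raise it unlikely. Together
#' with a symmetric proposal kernel this satisfies detailed balance with
#' respect to the Boltzmann weight \eqn{e^{-H}} (the Metropolis-Barker
#' algorithm).
#'
#' @param delta_h Numeric vector; +/-Inf map to 0 and 1.
#' @export
acceptance_probability <- function(delta_h) {
  ifelse(delta_h == Inf, 0, ifelse(delta_h == -Inf, 1, 1 / (exp(delta_h) + 1)))
}

new_count_series <- function(counts, frame_interval = 1) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  B <- ncol(counts)
  out <- tibble::as_tibble(counts, .name_repair = "minimal")
  names(out) <- paste0("bin_", seq_len(B))
  out <- dplyr::bind_cols(tibble::tibble(frame = seq_len(nrow(counts))), out)
  structure(out,
    frame_interval = frame_interval,
    class = c("count_series", class(out))
  )
}

#' Count-series accessors
#'
#' A count series is a tibble with a `frame` column and one `bin_<b>` column
#' per bin, carrying the seconds-per-frame interval as an attribute.
#' `counts_matrix()` returns the frames x bins integer matrix;
#' `frame_interval()` the sampling interval in seconds.
#'
#' @param counts A `count_series` tibble (or any data frame with a `frame`
#'   column and bin columns).
#' @export
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "frame"), drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' @rdname counts_matrix
#' @export
frame_interval <- function(counts) {
  fi <- attr(counts, "frame_interval")
  if (is.null(fi)) 1 else fi
}

#' Simulate a crowd on a bin lattice
#'
#' Runs the agent-based Markov chain: at each elementary step a random agent
#' contemplates a move to a random adjacent bin and executes it with the
#' Barker probability \eqn{1/(e^{\Delta H}+1)}. The stationary law of this
#' chain is the closed-system joint distribution
#' \eqn{P(\{N_b\}) \propto N_{tot}! \prod_b e^{-f_{N_b} - v_b N_b}/N_b!}.
#' One sweep is `n_agents` elementary steps, so the physical time per step
#' is inversely related to the crowd size and the sweep is the natural time
#' unit.
#'
#' @param model A [dfft_model]; `model$n_max` acts as the hard packing limit
#'   per bin.
#' @param lattice A [bin_lattice] with as many bins as `model$v`.
#' @param n_agents Number of agents; must not exceed `B * n_max`.
#' @param n_frames Number of frames to record after burn-in.
#' @param record_every Sweeps between recorded frames.
#' @param burn_in Burn-in sweeps before the first recorded frame.
#' @param initial One of `"uniform_random"` (each agent in a uniformly
#'   random bin, the worst-case mixing start) or `"stationary_heuristic"`
#'   (agents placed by sampling the model's independent-bin distribution,
#'   useful to shorten burn-in).
#' @param frame_interval Seconds per recorded frame stored in the output
#'   metadata (default `record_every`, i.e. one second per sweep).
#' @param seed Optional integer passed to [set.seed()] before sampling.
#' @return A `count_series` tibble (`frame` column plus one column per bin);
#'   every row sums to `n_agents`.
#' @examples
#' lat <- quasi1d_lattice(4)
#' m <- dfft_model(rep(0, 4), rep(0, 6))
#' sim <- simulate_crowd(m, lat, n_agents = 6, n_frames = 50, seed = 1)
#' @export
simulate_crowd <- function(model, lattice, n_agents,
                           n_frames = 600, record_every = 1L, burn_in = 100L,
                           initial = c("uniform_random", "stationary_heuristic"),
                           frame_interval = record_every, seed = NULL) {
  stopifnot(inherits(model, "dfft_model"), inherits(lattice, "bin_lattice"))
  initial <- match.arg(initial)
  B <- n_bins(lattice)
  if (length(model$v) != B) stop("model and lattice disagree on B", call. = FALSE)
  if (n_agents > B * model$n_max) {
    stop("infeasible placement: n_agents exceeds B * N_max", call. = FALSE)
  }
  stopifnot(record_every >= 1, n_frames >= 1, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)

  init <- place_agents(model, B, n_agents, initial)
  mat <- cpp_simulate(
    neighbor_slots(lattice), model$v, model$f, model$n_max,
    init, as.integer(n_frames), as.integer(record_every), as.integer(burn_in)
  )
  new_count_series(mat, frame_interval = frame_interval)
}

# initial placement respecting the per-bin cap
place_agents <- function(model, B, n_agents, initial) {
  probs <- if (initial == "stationary_heuristic") {
    pm <- prob_matrix(model)
    means <- as.numeric(pm %*% (0:model$n_max))
    means / sum(means)
  } else {
    rep(1 / B, B)
  }
  counts <- integer(B)
  bins <- integer(n_agents)
  for (a in seq_len(n_agents)) {
    open <- counts < model$n_max
    w <- probs * open
    if (sum(w) <= 0) w <- as.numeric(open)
    b <- sample.int(B, 1L, prob = w)
    bins[a] <- b
    counts[b] <- counts[b] + 1L
  }
  bins
}

#' Enumerate the exact stationary distribution of a small system
#'
#' Lists every occupancy configuration of `n_agents` agents over the bins
#' (respecting the `n_max` cap) with its exact normalized probability under
#' the closed-system law. Usable as an oracle for simulator output and, via
#' [transition_matrix()], for the chain itself.
#'
#' @inheritParams simulate_crowd
#' @param max_states Guard against combinatorial explosion (default 1e6).
#' @return A tibble with one row per configuration: columns `bin_1..bin_B`
#'   and `prob`, summing to 1.
#' @export
enumerate_stationary <- function(model, lattice, n_agents, max_states = 1e6) {
  B <- n_bins(lattice)
  states <- compositions(n_agents, B, model$n_max, max_states)
  lw <- apply(states, 1, function(s) log_joint_weight(model, s))
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  out <- tibble::as_tibble(states, .name_repair = "minimal")
  names(out) <- paste0("bin_", seq_len(B))
  out$prob <- p
  out
}

# all compositions of n into B parts, each part <= cap
compositions <- function(n, B, cap, max_states = 1e6) {
  n_comp <- choose(n + B - 1, B - 1)
  if (n_comp > max_states) {
    stop("too many configurations to enumerate (", format(n_comp), ")", call. = FALSE)
  }
  if (B == 1L) {
    if (n > cap) return(matrix(integer(0), ncol = 1))
    return(matrix(as.integer(n), ncol = 1))
  }
  rows <- list()
  for (k in 0:min(n, cap)) {
    sub <- compositions(n - k, B - 1L, cap, max_states)
    if (nrow(sub) > 0) rows[[length(rows) + 1L]] <- cbind(as.integer(k), sub)
  }
  if (length(rows) == 0) return(matrix(integer(0), ncol = B))
  do.call(rbind, rows)
}

#' Explicit transition matrix of the crowd Markov chain
#'
#' Builds the full transition matrix over the enumerable state space, using
#' the same proposal kernel as the simulator (uniform agent, uniform
#' proposal slot, missing slots and capacity violations rejected) and the
#' Barker acceptance rule. Its stationary left eigenvector is the exact
#' closed-system law, which makes it an independent oracle for both the
#' sampler and [enumerate_stationary()].
#'
#' @inheritParams enumerate_stationary
#' @return A list with `states` (matrix), `P` (row-stochastic transition
#'   matrix).
#' @export
transition_matrix <- function(model, lattice, n_agents, max_states = 2e4) {
  B <- n_bins(lattice)
  states <- compositions(n_agents, B, model$n_max, max_states)
  S <- nrow(states)
  key <- apply(states, 1, paste, collapse = ",")
  index <- stats::setNames(seq_len(S), key)
  slots <- neighbor_slots(lattice)
  D <- ncol(slots)
  P <- matrix(0, S, S)
  for (s in seq_len(S)) {
    occ <- states[s, ]
    stay <- 1
    for (from in seq_len(B)) {
      if (occ[from] == 0) next
      p_agent <- occ[from] / n_agents
      for (d in seq_len(D)) {
        to <- slots[from, d]
        if (is.na(to) || occ[to] >= model$n_max) next  # rejected proposal
        dh <- delta_H(model, occ, from, to)
        acc <- acceptance_probability(dh)
        occ2 <- occ
        occ2[from] <- occ2[from] - 1L
        occ2[to] <- occ2[to] + 1L
        t <- index[[paste(occ2, collapse = ",")]]
        w <- p_agent * (1 / D) * acc
        P[s, t] <- P[s, t] + w
        stay <- stay - w
      }
    }
    P[s, s] <- P[s, s] + stay
  }
  list(states = states, P = P)
}

#' Vexation shape generators
#'
#' Deterministic vexation profiles for synthetic arenas: `uniform` (zeros),
#' `linear_gradient` (0 to `amplitude`, e.g. a heat gradient along a
#' channel), `staircase` (piecewise-constant steps) and `hot_wall`
#' (quadratic ramp confined to the last third of the arena).
#'
#' @param profile Profile name.
#' @param B Number of bins.
#' @param amplitude Total vexation span in dimensionless units (agents'
#'   dissatisfaction enters probabilities as e^{-v}).
#' @param n_steps Number of plateaus for `staircase`.
#' @return Numeric vector of length B.
#' @export
make_vexation <- function(profile = c("uniform", "linear_gradient", "staircase", "hot_wall"),
                          B, amplitude = 1, n_steps = 4) {
  profile <- match.arg(profile)
  switch(profile,
    uniform = rep(0, B),
    linear_gradient = if (B == 1) 0 else amplitude * (seq_len(B) - 1) / (B - 1),
    staircase = {
      step <- ceiling(seq_len(B) / (B / n_steps))
      amplitude * (step - 1) / max(step - 1, 1)
    },
    hot_wall = {
      x <- seq_len(B) / B
      ramp <- pmax(0, (x - 2 / 3) / (1 / 3))
      amplitude * ramp^2
    }
  )
}

#' Frustration shape generators
#'
#' Families of occupancy interactions mirroring observed crowd "moods":
#' `neutral` (non-interacting, all zeros), `repulsive_quadratic`
#' (\eqn{f_N = c N(N-1)/2}, pairwise aversion with positive curvature),
#' `attractive_pairing` (negative curvature at N = 2, pair formation) and
#' `grouping` (attraction up to `group_size` then repulsion; the inflection
#' marks the preferred group density). All profiles satisfy the gauge
#' \eqn{f_0 = f_1 = 0}.
#'
#' @param profile Profile name.
#' @param n_max Maximum occupancy modeled.
#' @param strength Interaction strength c (dimensionless).
#' @param group_size Preferred occupancy for `grouping`.
#' @return Numeric vector \eqn{(f_0, \ldots, f_{N_{max}})}.
#' @export
make_frustration <- function(profile = c("neutral", "repulsive_quadratic",
                                         "attractive_pairing", "grouping"),
                             n_max, strength = 0.2, group_size = 8) {
  profile <- match.arg(profile)
  N <- 0:n_max
  f <- switch(profile,
    neutral = rep(0, n_max + 1),
    repulsive_quadratic = strength * N * (N - 1) / 2,
    attractive_pairing = {
      # downward bend at N = 2 (pair formation), neutral beyond
      f <- numeric(n_max + 1)
      if (n_max >= 2) f[3] <- -strength
      if (n_max >= 3) f[4:(n_max + 1)] <- -2.5 * strength
      f
    },
    grouping = {
      # cubic-like well: attractive below group_size, repulsive above,
      # inflection (sign change of the second difference) near group_size
      strength * ((N - group_size)^3 + group_size^3 - N * (3 * group_size^2 - 3 * group_size + 1)) / 6
    }
  )
  f[1:2] <- 0
  f
}
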