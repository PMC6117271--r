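# shared builders for small test systems

random_model <- function(B, n_max, v_range = c(-2, 2), f_range = c(-1, 2)) {
  f <- c(0, 0, stats::runif(max(n_max - 1, 0), f_range[1], f_range[2]))
  dfft_model(stats::runif(B, v_range[1], v_range[2]), f)
}

# stationary vector of a transition matrix via left eigen-decomposition
stationary_from_eigen <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# match enumerate_stationary() rows to transition_matrix() states
state_key <- function(m) apply(m, 1, paste, collapse = ",")

# Dirichlet draws through independent gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
    nrow = n
  )
  g / rowSums(g)
}

# the quasi-1D study setup: 48-bin gradient arena with quadratic repulsion
study_model <- function(amplitude = 4, strength = 0.2, n_max = 10) {
  dfft_model(
    make_vexation("linear_gradient", 48, amplitude = amplitude),
    make_frustration("repulsive_quadratic", n_max, strength = strength)
  )
}

study_lattice <- function() quasi1d_lattice(48)

# simulate and down-sample to ~independent frames (recording beyond the
# measured decorrelation time of ~11-15 sweeps for this chain)
study_counts <- function(model, n_agents, T_eff = 600, record_every = 15) {
  simulate_crowd(model, quasi1d_lattice(length(model$v)), n_agents,
    n_frames = T_eff, record_every = record_every, burn_in = 300,
    initial = "stationary_heuristic", frame_interval = 1
  )
}
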