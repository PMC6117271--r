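make_hist <- function(H, T_eff) {
  B <- nrow(H)
  n_max <- ncol(H) - 1L
  h <- tidyr::expand_grid(bin = seq_len(B), n = 0:n_max)
  h$hits <- as.integer(t(H)[cbind(h$n + 1L, h$bin)])
  attr(h, "T") <- as.integer(T_eff)
  class(h) <- c("occupancy_histograms", class(h))
  h
}

test_that("the objective matches closed forms for simple models", {
  H <- rbind(c(3L, 5L, 2L), c(6L, 3L, 1L))
  T_eff <- 10L
  h <- make_hist(H, T_eff)
  m0 <- dfft_model(c(0, 0), c(0, 0, 0))
  z <- 1 + 1 + 1 / 2
  expected <- T_eff * 2 * log(z) +
    sum(H %*% lfactorial(0:2)) # v N and f terms vanish
  expect_equal(neg_log_posterior(m0, h), expected, tolerance = 1e-12)
  # prior arithmetic: v = 15 in one bin adds exactly 1/2 at sigma = 15
  m1 <- dfft_model(c(15, 0), c(0, 0, 0))
  base <- sum(sapply(1:2, function(b) {
    lw <- -m1$v[b] * (0:2) - lfactorial(0:2)
    T_eff * log(sum(exp(lw))) + sum(H[b, ] * (m1$v[b] * (0:2) + lfactorial(0:2)))
  }))
  expect_equal(neg_log_posterior(m1, h), base + 0.5, tolerance = 1e-10)
})

test_that("histogram-route objective equals a frame-by-frame evaluation", {
  set.seed(41)
  B <- 5
  n_max <- 6
  m <- random_model(B, n_max)
  cm <- matrix(sample(0:n_max, 40 * B, replace = TRUE), ncol = B)
  counts <- dfft:::new_count_series(cm)
  h <- occupancy_histograms(counts, tau = 1, n_max = n_max)
  via_hist <- neg_log_posterior(m, h, prior_sigma = 15)
  # independent re-implementation: loop over frames and bins directly
  lz <- sapply(seq_len(B), function(b) {
    log(sum(exp(-m$v[b] * (0:n_max) - m$f - lfactorial(0:n_max))))
  })
  frame_terms <- 0
  for (t in seq_len(nrow(cm))) {
    for (b in seq_len(B)) {
      N <- cm[t, b]
      frame_terms <- frame_terms + m$v[b] * N + lfactorial(N) + m$f[N + 1]
    }
  }
  via_frames <- nrow(cm) * sum(lz) + frame_terms +
    sum(m$f^2) / (2 * 15^2) + sum(m$v^2) / (2 * 15^2)
  expect_equal(via_hist, via_frames, tolerance = 1e-9 * abs(via_frames))
})

test_that("a tiny MAP fit matches an iteratively refined grid search", {
  set.seed(42)
  m_true <- dfft_model(c(0.2, -0.4), c(0, 0, 0.6, 0.1))
  sim <- simulate_crowd(m_true, quasi1d_lattice(2), 3,
    n_frames = 400,
    record_every = 10, burn_in = 100
  )
  h <- occupancy_histograms(sim, tau = 1, n_max = 3)
  fit <- fit_dfft(h, n_max = 3)
  # brute-force oracle: shrinking dense grids over (f_2, f_3, v_1, v_2)
  H <- dfft:::hits_matrix(h)
  T_eff <- n_samples(h)
  center <- c(0, 0, 0, 0)
  width <- 4
  for (round in 1:12) {
    axes <- lapply(center, function(c0) seq(c0 - width, c0 + width, length.out = 7))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, dfft:::nlp_objective,
      B = 2, n_max = 3, H = H,
      T_eff = T_eff, prior_sigma = 15
    )
    center <- grid[which.min(vals), ]
    width <- width / 2.5
  }
  est <- c(fit$model$f[3:4], fit$model$v)
  expect_equal(unname(est), unname(center), tolerance = 1e-4)
})

test_that("null data yield frustrations consistent with zero", {
  set.seed(43)
  B <- 16
  m <- dfft_model(rep(0, B), rep(0, 9))
  sim <- study_counts(m, 32, T_eff = 600)
  fit <- fit_dfft(occupancy_histograms(sim, tau = 1))
  td <- tidy(fit)
  f_terms <- td[grepl("^f_", td$term), ]
  expect_gte(mean(abs(f_terms$estimate) <= 2 * f_terms$std.error), 0.9)
})

test_that("optimization is convex: distant starts reach the same optimum", {
  set.seed(44)
  m <- random_model(3, 4)
  sim <- simulate_crowd(m, quasi1d_lattice(3), 6,
    n_frames = 300,
    record_every = 8, burn_in = 100
  )
  h <- occupancy_histograms(sim, tau = 1, n_max = 4)
  H <- dfft:::hits_matrix(h)
  T_eff <- n_samples(h)
  fits <- lapply(c(0, 2, -2), function(s) {
    stats::optim(rep(s, 3 + 3), dfft:::nlp_objective, dfft:::nlp_gradient,
      B = 3, n_max = 4, H = H, T_eff = T_eff, prior_sigma = 15,
      method = "BFGS", control = list(maxit = 2000, reltol = 1e-15)
    )$par
  })
  expect_equal(fits[[1]], fits[[2]], tolerance = 1e-6)
  expect_equal(fits[[1]], fits[[3]], tolerance = 1e-6)
})

test_that("Fisher information matches the numerical Hessian and Poisson identities", {
  set.seed(45)
  # single neutral bin with mean 2: I_vv = T * lambda
  lam <- 2
  n_max <- 25
  m1 <- dfft_model(-log(lam), rep(0, n_max + 1))
  I1 <- fisher_information(m1, T_eff = 100)
  expect_equal(unname(I1["v_1", "v_1"]), 100 * lam, tolerance = 1e-6)

  # full matrix against central finite differences of the likelihood
  m <- random_model(3, 4)
  T_eff <- 73
  N <- 0:4
  obj_full <- function(th) {
    f <- th[1:5]
    v <- th[6:8]
    sum(sapply(1:3, function(b) {
      lw <- -v[b] * N - f - lfactorial(N)
      mx <- max(lw)
      T_eff * (mx + log(sum(exp(lw - mx))))
    }))
  }
  th0 <- c(m$f, m$v)
  hstep <- 1e-3
  n_p <- length(th0)
  Hm <- matrix(0, n_p, n_p)
  for (i in seq_len(n_p)) {
    for (j in seq_len(n_p)) {
      ei <- ej <- numeric(n_p)
      ei[i] <- hstep
      ej[j] <- hstep
      Hm[i, j] <- (obj_full(th0 + ei + ej) - obj_full(th0 + ei - ej) -
        obj_full(th0 - ei + ej) + obj_full(th0 - ei - ej)) / (4 * hstep^2)
    }
  }
  I <- fisher_information(m, T_eff, gauge_fixed = FALSE)
  expect_lt(max(abs(I - Hm)) / max(abs(I)), 1e-5)
})

test_that("the unfixed Fisher matrix annihilates both gauge directions", {
  set.seed(46)
  m <- random_model(4, 5)
  I <- fisher_information(m, T_eff = 200, gauge_fixed = FALSE)
  beta_dir <- c(rep(1, 6), rep(0, 4))
  alpha_dir <- c(0:5, rep(-1, 4))
  scale <- max(abs(I))
  expect_lt(max(abs(I %*% beta_dir)) / scale, 1e-8)
  expect_lt(max(abs(I %*% alpha_dir)) / scale, 1e-8)
  # gauge fixing removes the singularity
  Ig <- fisher_information(m, T_eff = 200)
  expect_true(all(eigen(Ig, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("parameter covariance inverts the information and scales as 1/T", {
  # single-bin Poisson: var(v) = 1/(T lambda)
  lam <- 3
  m1 <- dfft_model(-log(lam), rep(0, 31))
  fit_like <- structure(
    list(model = m1, T = 500, prior_sigma = 15, interactions = FALSE),
    class = "dfft_fit"
  )
  cov1 <- parameter_covariance(fit_like)
  expect_equal(unname(cov1[1, 1]), 1 / (500 * lam), tolerance = 1e-6)

  set.seed(47)
  m <- random_model(4, 5)
  fitA <- structure(list(model = m, T = 300, prior_sigma = 15, interactions = TRUE),
    class = "dfft_fit"
  )
  fitB <- structure(list(model = m, T = 600, prior_sigma = 15, interactions = TRUE),
    class = "dfft_fit"
  )
  covA <- parameter_covariance(fitA)
  covB <- parameter_covariance(fitB)
  expect_equal(max(abs(covB / covA - 0.5)), 0, tolerance = 0.05)
  expect_equal(covA, t(covA), tolerance = 1e-10)
})

test_that("vexation-only fits recover the Poisson maximum likelihood", {
  set.seed(48)
  # bin with sample mean 2.0 and a negligible prior: e^{-v} = 2
  cm <- cbind(as.integer(rpois(2000, 2.0)))
  counts <- dfft:::new_count_series(cm)
  h <- occupancy_histograms(counts, tau = 1, n_max = 12)
  fit <- fit_poisson(h, n_max = 12, prior_sigma = 1e4)
  expect_equal(exp(-fit$model$v[1]), mean(cm), tolerance = 1e-3)
  expect_true(all(fit$model$f == 0))
})

test_that("model comparison calibrates on true-model data and detects misfit", {
  set.seed(49)
  m <- study_model(strength = 0.2)
  sim <- study_counts(m, 65, T_eff = 600)
  h <- occupancy_histograms(sim, tau = 1)
  fit_full <- fit_dfft(h, n_max = 10)
  fit_pois <- fit_poisson(h, n_max = 10)
  cmp <- model_comparison(fit_full, fit_pois)
  expect_gte(attr(cmp, "lrt_stat"), 0)
  # the DFFT fit explains its own data: reduced chi-squared near 1
  expect_gt(cmp$chisq_reduced[cmp$model == "dfft"], 0.6)
  expect_lt(cmp$chisq_reduced[cmp$model == "dfft"], 1.5)
  # a vexation-only fit cannot absorb strong repulsion
  expect_gt(cmp$chisq_reduced[cmp$model == "poisson"], 2)
  expect_lt(attr(cmp, "lrt_p"), 0.001)
})

test_that("the likelihood-ratio test keeps its size on neutral data", {
  # null replicates drawn from the model's own occupancy law (independent
  # Poisson bins, the complete-spatial-randomness null); closed-system
  # simulation adds a small fixed-N_tot noncentrality discussed in the
  # vignette and checked separately below
  set.seed(50)
  rejections <- 0
  n_rep <- 20
  B <- 12
  T_eff <- 250
  for (r in seq_len(n_rep)) {
    cm <- matrix(rpois(T_eff * B, 1.5), ncol = B)
    h <- occupancy_histograms(dfft:::new_count_series(cm), tau = 1)
    ff <- fit_dfft(h)
    fp <- fit_poisson(h, n_max = ff$model$n_max)
    cmp <- model_comparison(ff, fp)
    if (attr(cmp, "lrt_p") < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.1 + 1e-9)
})

test_that("closed-system null simulations inflate the LRT only mildly", {
  # fixing N_tot couples the bins and adds curvature of order
  # N(N-1)/(2 sum_b Var_b) to the apparent frustration; at fly-like scale
  # that shifts the LRT statistic by a few units, no more
  set.seed(54)
  B <- 48
  m <- dfft_model(rep(0, B), rep(0, 16))
  stats <- replicate(8, {
    sim <- study_counts(m, 65, T_eff = 250, record_every = 30)
    h <- occupancy_histograms(sim, tau = 1)
    ff <- fit_dfft(h)
    fp <- fit_poisson(h, n_max = ff$model$n_max)
    cmp <- model_comparison(ff, fp)
    attr(cmp, "lrt_stat") - attr(cmp, "lrt_dof")
  })
  expect_lt(mean(stats), 12)
  expect_gt(mean(stats), -5)
})

test_that("prior sensitivity reports a modest shift for well-identified fits", {
  set.seed(51)
  m <- study_model(strength = 0.2)
  sim <- study_counts(m, 65, T_eff = 600)
  fit <- fit_dfft(occupancy_histograms(sim, tau = 1), n_max = 10)
  sens <- prior_sensitivity(fit, tight_sigma = 1)
  expect_lt(sens$relative_change, 0.5)
  expect_gte(sens$relative_change, 0)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(52)
  m <- random_model(3, 4)
  sim <- simulate_crowd(m, quasi1d_lattice(3), 6,
    n_frames = 200,
    record_every = 8, burn_in = 50
  )
  fit <- fit_dfft(occupancy_histograms(sim, tau = 1, n_max = 4), n_max = 4)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), (4 - 1) + 3)
  gl <- glance(fit)
  expect_equal(gl$B, 3)
  expect_true(gl$converged)
})
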