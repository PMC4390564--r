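test_that("sampler matches a grid-integration posterior on the intercept model", {
  n <- 30
  ped <- pedigree(1:n, rep(0, n), rep(0, n))
  set.seed(21)
  y <- rnorm(n, 12, 2)
  dat <- data.frame(id = 1:n, y = y)
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped,
                    genetic = FALSE, epigenetic = FALSE)
  fit <- run_gibbs(spec, prior_spec(),
                   gibbs_config(n_iter = 30000, burn_in = 2000, thin = 1,
                                seed = 22, store_effects = TRUE))
  # independent oracle: 2-D quadrature over (mu, sigma2) of the flat-prior
  # posterior  prod N(y_i; mu, sigma2)
  mugrid <- seq(mean(y) - 4 * sd(y) / sqrt(n), mean(y) + 4 * sd(y) / sqrt(n),
                length.out = 400)
  s2grid <- seq(1e-3, 6 * var(y), length.out = 600)
  lp <- outer(mugrid, s2grid, function(m, s2)
    -n / 2 * log(s2) - (sum((y - mean(y))^2) + n * (mean(y) - m)^2) /
      (2 * s2))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  mu_mean <- sum(rowSums(p) * mugrid)
  mu_var <- sum(rowSums(p) * mugrid^2) - mu_mean^2
  s2_mean <- sum(colSums(p) * s2grid)

  mu_draws <- fit$effects[, 1]
  expect_equal(mean(mu_draws), mu_mean, tolerance = 0.01)
  expect_equal(var(mu_draws), mu_var, tolerance = 0.05)
  expect_equal(mean(fit$draws[, "sigma_e2"]), s2_mean, tolerance = 0.05)
})

test_that("without the w term the sampler is a standard animal model", {
  sim <- simulate_population(sim_config(n_base = 200, n_families = 100,
    family_size = 3, n_generations = 2, sigma_u2 = 210, sigma_w2 = 0,
    sigma_e2 = 390, lambda = 0.3, seed = 23))
  dat <- data.frame(id = sim$pedigree$label, y = sim$y)
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = sim$pedigree,
                    epigenetic = FALSE)
  fit <- run_gibbs(spec, prior_spec(),
                   gibbs_config(n_iter = 6000, burn_in = 1000, thin = 2,
                                seed = 24))
  expect_false(any(c("sigma_w2", "lambda") %in% colnames(fit$draws)))
  su <- fit$draws[, "sigma_u2"]
  se <- fit$draws[, "sigma_e2"]
  expect_gt(210, hpd_interval(su)[1]); expect_lt(210, hpd_interval(su)[2])
  expect_gt(390, hpd_interval(se)[1]); expect_lt(390, hpd_interval(se)[2])
  h2 <- fit$draws[, "h2"]
  expect_equal(mean(h2), 0.35, tolerance = 0.3)
})

test_that("degenerate structure (founders only) stays stable and finite", {
  n <- 150
  ped <- pedigree(1:n, rep(0, n), rep(0, n))
  set.seed(25)
  dat <- data.frame(id = 1:n, y = rnorm(n, 100, 10))
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped)
  expect_warning(
    fit <- run_gibbs(spec, prior_spec(),
                     gibbs_config(n_iter = 10000, burn_in = 0, thin = 10,
                                  seed = 26)),
    "unidentifiable")
  expect_true(all(is.finite(fit$draws)))
  # lambda is its uniform(0, 0.5) prior here (Monte Carlo tolerance)
  expect_equal(mean(fit$draws[, "lambda"]), 0.25, tolerance = 0.08)
})

test_that("chains are reproducible and resumable", {
  tm <- toy_model(seed = 27)
  cfgA <- gibbs_config(n_iter = 400, burn_in = 0, thin = 1, seed = 13)
  fitA <- run_gibbs(tm$spec, config = cfgA)
  fitA2 <- run_gibbs(tm$spec, config = cfgA)
  expect_identical(fitA$draws, fitA2$draws)

  cfgB <- gibbs_config(n_iter = 200, burn_in = 0, thin = 1, seed = 13)
  fitB <- run_gibbs(tm$spec, config = cfgB)
  cfgC <- gibbs_config(n_iter = 200, burn_in = 0, thin = 1, seed = NULL)
  fitC <- run_gibbs(tm$spec, config = cfgC, init = fitB$state)
  expect_equal(rbind(fitB$draws, fitC$draws), fitA$draws,
               tolerance = 1e-12)
})

test_that("stored fitted values equal the incidence times stored effects", {
  tm <- toy_model(seed = 28)
  fit <- run_gibbs(tm$spec, config = gibbs_config(
    n_iter = 200, burn_in = 100, thin = 10, seed = 29,
    store_effects = TRUE, store_fitted = TRUE))
  layout <- epivar:::model_layout(tm$spec)
  W <- epivar:::incidence_matrix(tm$spec, layout)
  for (k in seq_len(nrow(fit$fitted))) {
    expect_equal(fit$fitted[k, ],
                 as.numeric(W %*% fit$effects[k, ]), tolerance = 1e-12)
  }
})

test_that("MME solutions are equivariant under pedigree relabelling", {
  plain <- random_pedigree(n = 60, seed = 30, shuffle = FALSE)
  mixed <- random_pedigree(n = 60, seed = 30, shuffle = TRUE)
  set.seed(31)
  y <- rnorm(60, 20, 3)
  v <- list(sigma_u2 = 2, sigma_w2 = 1, sigma_e2 = 3, lambda = 0.25)
  dat1 <- data.frame(id = plain$label, y = y)
  s1 <- local({
    m <- build_mme(epi_model(y ~ 1, dat1, "id", plain), v)
    as.numeric(Matrix::solve(m$C, m$r))
  })
  # same individuals under reversed labels, presented shuffled
  dat2 <- data.frame(id = as.character(100L + 61L - seq_len(60L)), y = y)
  s2 <- local({
    m <- build_mme(epi_model(y ~ 1, dat2, "id", mixed), v)
    as.numeric(Matrix::solve(m$C, m$r))
  })
  map <- match(as.character(100L + 61L - seq_len(60L)), mixed$label)
  expect_equal(s1[1], s2[1], tolerance = 1e-8)                  # intercept
  expect_equal(s1[1 + seq_len(60)], s2[1 + map], tolerance = 1e-8)   # u
  expect_equal(s1[61 + seq_len(60)], s2[61 + map], tolerance = 1e-8) # w
})

test_that("successive-conditional simulation recovers the priors", {
  # Geweke-style joint check: alternate y | theta with one full Gibbs
  # cycle of theta | y (exact lambda update); the marginal law of theta
  # must remain the prior.
  sim <- simulate_population(sim_config(n_base = 10, n_families = 10,
    family_size = 2, n_generations = 1, sigma_u2 = 1, sigma_w2 = 1,
    sigma_e2 = 1, lambda = 0.25, seed = 32))
  ped <- sim$pedigree
  n <- ped$n
  A <- build_A_tabular(ped)
  cA <- t(chol(A))
  priors <- prior_spec(sigma_u2 = c(4, 6), sigma_w2 = c(4, 6),
                       sigma_e2 = c(4, 6))
  cfg <- gibbs_config(n_iter = 1, burn_in = 0, thin = 1, seed = NULL,
                      lambda_update = "metropolis_exact")

  set.seed(33)
  lam <- runif(1, 0, 0.5)
  sigs <- 4 / rchisq(3, 6)                      # prior draws (u, w, e)
  u <- as.numeric(cA %*% rnorm(n)) * sqrt(sigs[1])
  w <- as.numeric(t(chol(build_T(ped, lam))) %*% rnorm(n)) * sqrt(sigs[2])
  state <- list(s = c(u, w), lambda = lam, sigma_u2 = sigs[1],
                sigma_w2 = sigs[2], sigma_e2 = sigs[3],
                G = diag(2), sigma_iid = numeric(0))
  M <- 4000
  out <- matrix(0, M, 4,
                dimnames = list(NULL, c("sigma_u2", "sigma_w2",
                                        "sigma_e2", "lambda")))
  for (it in seq_len(M)) {
    y <- state$s[seq_len(n)] + state$s[n + seq_len(n)] +
      rnorm(n, 0, sqrt(state$sigma_e2))
    dat <- data.frame(id = ped$label, y = y)
    spec <- epi_model(y ~ 0, dat, id = "id", pedigree = ped)
    fit <- run_gibbs(spec, priors, cfg, init = state)
    state <- fit$state
    out[it, ] <- fit$draws[1, colnames(out)]
  }
  # prior of each variance: 4 / chisq(6); of lambda: uniform(0, 0.5)
  for (v in c("sigma_u2", "sigma_w2", "sigma_e2")) {
    x <- out[, v]
    ess <- max(effective_size(x), 50)
    # P(sigma2 <= 1) = P(chisq_6 >= 4), a tail-robust location check
    p_ref <- 1 - pchisq(4, 6)
    expect_equal(mean(x <= 1), p_ref,
                 tolerance = 5 * sqrt(p_ref * (1 - p_ref) / ess))
    expect_equal(mean(x), 1, tolerance = 5 * sd(x) / sqrt(ess) + 0.05)
  }
  lam_chain <- out[, "lambda"]
  ess_l <- max(effective_size(lam_chain), 50)
  expect_equal(mean(lam_chain), 0.25,
               tolerance = 5 * sd(lam_chain) / sqrt(ess_l))
  expect_equal(var(lam_chain), 1 / 48, tolerance = 0.3)
  expect_equal(mean(lam_chain <= 0.125), 0.25, tolerance = 0.06)
})
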