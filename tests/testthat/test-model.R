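test_that("model specification validates its inputs", {
  ped <- fig1_pedigree()
  dat <- data.frame(id = 1:7, y = rnorm(7), grp = gl(2, 4)[1:7])
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped)
  expect_s3_class(spec, "epi_model_spec")
  expect_identical(ncol(spec$X), 1L)
  expect_error(epi_model(y ~ 1, transform(dat, id = c(1:6, 99)),
                         id = "id", pedigree = ped), "not in the pedigree")
  expect_error(epi_model(y ~ 1, dat, id = "id", pedigree = ped,
                         maternal = "id", genetic = FALSE),
               "requires genetic")
  spec2 <- epi_model(y ~ 1, dat, id = "id", pedigree = ped, random = "grp")
  expect_identical(spec2$iid$grp$size, 2L)
})

test_that("mixed-model equations reproduce the dense GLS solution", {
  ped <- fig1_pedigree()
  set.seed(99)
  y <- 10 + rnorm(7, sd = 3)
  dat <- data.frame(id = 1:7, y = y)
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped)
  v <- list(sigma_u2 = 2.5, sigma_w2 = 1.5, sigma_e2 = 3, lambda = 0.3)
  mme <- build_mme(spec, v)
  s <- as.numeric(Matrix::solve(mme$C, mme$r))

  # dense oracle: V = A su2 + T sw2 + I se2 (Z = I here)
  A <- build_A_tabular(ped)
  TT <- build_T(ped, 0.3)
  V <- A * v$sigma_u2 + TT * v$sigma_w2 + diag(7) * v$sigma_e2
  Vi <- solve(V)
  X <- matrix(1, 7, 1)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% b
  u <- v$sigma_u2 * A %*% Vi %*% resid
  w <- v$sigma_w2 * TT %*% Vi %*% resid
  expect_equal(s, c(b, u, w), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("intercept-only equations collapse to n and sum(y)", {
  ped <- pedigree(1:3, c(0, 0, 0), c(0, 0, 0))
  dat <- data.frame(id = 1:3, y = c(1, 2, 6))
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped,
                    genetic = FALSE, epigenetic = FALSE)
  mme <- build_mme(spec, list(sigma_e2 = 1))
  expect_equal(as.matrix(mme$C), matrix(3), ignore_attr = TRUE)
  expect_equal(mme$r, 9)
  # one founder with one record, u-term only: u-block diagonal is 1 + alpha
  spec1 <- epi_model(y ~ 0, data.frame(id = 1, y = 2), id = "id",
                     pedigree = pedigree(1, 0, 0), epigenetic = FALSE)
  m1 <- build_mme(spec1, list(sigma_u2 = 2, sigma_e2 = 4))
  expect_equal(as.matrix(m1$C), matrix(1 + 2), ignore_attr = TRUE)
})

test_that("sampler plan assembly agrees with build_mme across models", {
  # u + w + an identity-structured term
  tm <- toy_model()
  tm$dat$gen <- factor(tm$sim$generation)
  spec <- epi_model(y ~ 1, tm$dat, id = "id", pedigree = tm$sim$pedigree,
                    random = "gen")
  v <- list(sigma_u2 = 150, sigma_w2 = 80, sigma_e2 = 300, lambda = 0.2,
            gen = 40)
  C1 <- build_mme(spec, v)$C
  C2 <- epivar:::plan_C(epivar:::gibbs_plan(spec), v)
  expect_lt(max(abs(C1 - C2)), 1e-10)

  # correlated direct/maternal pair
  sim <- tm$sim
  known <- sim$pedigree$dam > 0L
  dat <- data.frame(id = sim$pedigree$label[known],
                    dam = sim$pedigree$label[sim$pedigree$dam[known]],
                    y = sim$y[known])
  spec2 <- epi_model(y ~ 1, dat, id = "id", pedigree = sim$pedigree,
                     maternal = "dam")
  v2 <- list(G = matrix(c(100, -30, -30, 50), 2), sigma_w2 = 80,
             sigma_e2 = 300, lambda = 0.35)
  C3 <- build_mme(spec2, v2)$C
  C4 <- epivar:::plan_C(epivar:::gibbs_plan(spec2), v2)
  expect_lt(max(abs(C3 - C4)), 1e-10)
})

test_that("single-site location sweep targets sigma_e2 * C^-1", {
  # intercept-only system: posterior N(mean(y), sigma_e2 / n)
  ped <- pedigree(1:20, rep(0, 20), rep(0, 20))
  set.seed(5)
  dat <- data.frame(id = 1:20, y = rnorm(20, 50, 4))
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = ped,
                    genetic = FALSE, epigenetic = FALSE)
  sys <- build_mme(spec, list(sigma_e2 = 9))
  set.seed(1)
  mu <- replicate(2e4, sample_location(sys, 9)[1])
  expect_equal(mean(mu), mean(dat$y), tolerance = 0.01)
  expect_equal(var(mu), 9 / 20, tolerance = 0.03)

  # two-coordinate system with a correlated C: joint covariance
  C <- Matrix::Matrix(c(2, 0.8, 0.8, 1.5), 2, sparse = TRUE)
  sys2 <- list(C = C, r = c(1, 2), s = c(0, 0))
  set.seed(2)
  s <- c(0, 0)
  draws <- matrix(0, 2e4, 2)
  for (i in seq_len(nrow(draws))) {
    s <- sample_location(sys2, 2, s = s)
    draws[i, ] <- s
  }
  Cinv <- solve(as.matrix(C))
  expect_equal(colMeans(draws), as.numeric(Cinv %*% c(1, 2)),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(cov(draws), 2 * Cinv, tolerance = 0.05, ignore_attr = TRUE)

  # a coordinate whose r_i equals sum c_ij s_j draws around zero
  expect_error(sample_location(sys2, -1))
})

test_that("variance draws follow the scaled inverse chi-square", {
  set.seed(3)
  d <- replicate(2e4, sample_variance(100, 52, 0, -2))
  # mean of (q + s2)/chisq(nu) is (q + s2)/(nu - 2) = 100/48
  se <- sqrt(2 * 100^2 / (48^2 * 46) / 2e4)
  expect_equal(mean(d), 100 / 48, tolerance = 5 * se / (100 / 48))
  # zero data: draws come from the prior itself
  set.seed(4)
  p <- replicate(2e4, sample_variance(0, 0, prior_s2 = 6, prior_n = 8))
  expect_equal(mean(p), 6 / (8 - 2), tolerance = 0.03)
  expect_error(sample_variance(10, 2, 0, -2, label = "sigma_x2"),
               "sigma_x2")
  expect_error(sample_variance(-1, 10))
})

test_that("G draws follow the inverse-Wishart conditional", {
  # flat data-free case with an informative prior: mean G0/(df - 3)
  n <- 10
  Ainv <- Matrix::Diagonal(n)
  G0 <- matrix(c(4, 1, 1, 3), 2)
  set.seed(6)
  draws <- replicate(4000, sample_G(rep(0, n), rep(0, n), Ainv,
                                    n_G = 8, G0 = G0))
  expect_equal(apply(draws, 1:2, mean), G0 / (n + 8 - 3),
               tolerance = 0.05)
  # with data: scale is the A^-1-weighted cross-product matrix
  ped <- fig1_pedigree()
  Ai <- build_A_inverse(ped)
  set.seed(7)
  u <- rnorm(7); m <- rnorm(7)
  S <- matrix(c(sum(u * (Ai %*% u)), sum(u * (Ai %*% m)),
                sum(u * (Ai %*% m)), sum(m * (Ai %*% m))), 2) + G0
  dd <- replicate(4000, sample_G(u, m, Ai, n_G = 8, G0 = G0))
  expect_equal(apply(dd, 1:2, mean), S / (7 + 8 - 3), tolerance = 0.08)
  expect_error(sample_G(u, m, Ai, n_G = -7), "exceed 1")
})

test_that("lambda TN conditional matches the hand-evaluated trio", {
  ped <- pedigree(1:3, c(0, 0, 1), c(0, 0, 2))
  w <- c(1, 1, 0.6)
  st <- epivar:::cpp_lambda_stats(ped$sire, ped$dam, w)
  expect_equal(unname(st), c(2 * 0.6, 4, 0, 0))
  # at current lambda 0.3, sigma_w2 = 1: mu = (1.2/0.82)/(4/0.82) = 0.3
  db <- 1 - 2 * 0.3^2
  mu <- (st[["cross_both"]] / db) / (st[["sq_both"]] / db)
  expect_equal(mu, 0.3)
  sd_lam <- sqrt(1 / (st[["sq_both"]] / db))

  # the TN density with these parameters equals the normalised fixed-d
  # conditional exp(-(w3 - lam(w1+w2))^2 / (2 d sigma_w2)) on a grid
  grid <- seq(0.00025, 0.49975, length.out = 1000)
  f1 <- dnorm(grid, mu, sd_lam)
  f1 <- f1 / sum(f1)
  f2 <- exp(-(w[3] - grid * (w[1] + w[2]))^2 / (2 * db))
  f2 <- f2 / sum(f2)
  expect_lt(max(abs(f1 - f2)), 1e-12)

  # draws follow that truncated normal (moment check against the grid)
  set.seed(8)
  d <- replicate(2e4, sample_lambda(w, ped, 1, 0.3))
  expect_equal(mean(d), sum(grid * f1), tolerance = 0.005)
  expect_equal(sd(d), sqrt(sum(grid^2 * f1) - sum(grid * f1)^2),
               tolerance = 0.01)
})

test_that("lambda falls back to its prior when data are uninformative", {
  ped <- pedigree(1:3, c(0, 0, 1), c(0, 0, 2))
  set.seed(9)
  d <- replicate(5000, sample_lambda(c(0, 0, 0.5), ped, 1, 0.2))
  expect_equal(mean(d), 0.25, tolerance = 0.01)   # uniform(0, 0.5)
  expect_gt(min(d), 0); expect_lt(max(d), 0.5)
  founders <- pedigree(1:4, rep(0, 4), rep(0, 4))
  expect_warning(sample_lambda(rnorm(4), founders, 1, 0.2),
                 "unidentifiable")
})

test_that("metropolis_exact lambda draws match a grid-integration oracle", {
  sim <- simulate_population(sim_config(n_base = 60, n_families = 35,
    family_size = 4, n_generations = 1, sigma_u2 = 0, sigma_w2 = 1,
    sigma_e2 = 0.01, lambda = 0.3, seed = 10))
  ped <- sim$pedigree
  w <- sim$w
  sigw2 <- 1

  grid <- seq(0.00025, 0.49975, length.out = 1000)
  ld <- vapply(grid, function(l)
    epivar:::cpp_lambda_logdens(l, ped$sire, ped$dam, w, sigw2), numeric(1))
  f <- exp(ld - max(ld)); f <- f / sum(f)
  target_mean <- sum(grid * f)
  target_sd <- sqrt(sum(grid^2 * f) - target_mean^2)

  set.seed(11)
  lam <- 0.25
  chain <- numeric(15000)
  for (i in seq_along(chain)) {
    lam <- as.numeric(sample_lambda(w, ped, sigw2, lam,
                                    mode = "metropolis_exact"))
    chain[i] <- lam
  }
  chain <- chain[-(1:500)]
  expect_equal(mean(chain), target_mean, tolerance = 4 * target_sd /
                 sqrt(effective_size(chain)) / target_mean)
  expect_equal(sd(chain), target_sd, tolerance = 0.15)
  # distribution-level agreement: CDF at the quartiles of the grid law
  for (q in c(0.25, 0.5, 0.75)) {
    qv <- grid[which.min(abs(cumsum(f) - q))]
    expect_equal(mean(chain <= qv), q, tolerance = 0.05)
  }
})
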