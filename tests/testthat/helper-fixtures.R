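# Shared fixtures, all built in code.

# Seven-individual worked example: 1, 2, 3 founders; 4 = 1 x 2; 5 = 1 x 3;
# 6 = 1 x 3; 7 = 6 x unknown.
fig1_pedigree <- function() {
  pedigree(id = 1:7,
           sire = c(0, 0, 0, 1, 1, 1, 6),
           dam  = c(0, 0, 0, 2, 3, 3, 0))
}

# The symbolic T matrix of the worked example, as a function of lambda.
fig1_T <- function(l) {
  rbind(c(1,   0, 0,   l,     l,       l,       l^2),
        c(0,   1, 0,   l,     0,       0,       0),
        c(0,   0, 1,   0,     l,       l,       l^2),
        c(l,   l, 0,   1,     l^2,     l^2,     l^3),
        c(l,   0, l,   l^2,   1,       2*l^2,   2*l^3),
        c(l,   0, l,   l^2,   2*l^2,   1,       l),
        c(l^2, 0, l^2, l^3,   2*l^3,   l,       1))
}

# Random pedigree: founders followed by individuals whose parents are any
# earlier individuals (so inbreeding and cross-generation matings occur);
# a fraction has a single known parent. Labels can be shuffled to exercise
# the topological reordering.
random_pedigree <- function(n = 100, n_founders = max(4, round(n / 5)),
                            p_single = 0.1, seed = 1, shuffle = FALSE) {
  set.seed(seed)
  sire <- integer(n)
  dam <- integer(n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1L)
    if (runif(1) < p_single) {
      sire[i] <- sample(pool, 1)
    } else {
      pick <- sample(pool, 2)
      sire[i] <- pick[1]
      dam[i] <- pick[2]
    }
  }
  if (shuffle) {
    # new label of original individual i is 100 + n + 1 - i (reversed),
    # so tests can reconstruct the correspondence
    lab <- 100L + n + 1L - seq_len(n)
    rows <- sample.int(n)                 # records presented out of order
    s2 <- integer(n); s2[sire > 0L] <- lab[sire[sire > 0L]]
    d2 <- integer(n); d2[dam > 0L] <- lab[dam[dam > 0L]]
    pedigree(id = lab[rows], sire = s2[rows], dam = d2[rows])
  } else {
    pedigree(seq_len(n), sire, dam)
  }
}

# Non-inbred random pedigree: founders plus one generation whose parents
# are distinct founders, so no mating pair is related.
random_noninbred_pedigree <- function(n_founders = 40, n_offspring = 60,
                                      p_single = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_offspring
  sire <- integer(n)
  dam <- integer(n)
  for (i in (n_founders + 1):n) {
    pick <- sample(n_founders, 2)
    sire[i] <- pick[1]
    if (runif(1) >= p_single) dam[i] <- pick[2]
  }
  pedigree(seq_len(n), sire, dam)
}

# Tiny dataset + model spec used by several sampler tests.
toy_model <- function(n_base = 40, n_families = 20, family_size = 3,
                      n_generations = 2, sigma_u2 = 210, sigma_w2 = 120,
                      sigma_e2 = 270, lambda = 0.3, seed = 7, ...) {
  sim <- simulate_population(sim_config(
    n_base = n_base, n_families = n_families, family_size = family_size,
    n_generations = n_generations, sigma_u2 = sigma_u2,
    sigma_w2 = sigma_w2, sigma_e2 = sigma_e2, lambda = lambda,
    seed = seed))
  dat <- data.frame(id = sim$pedigree$label, y = sim$y)
  spec <- epi_model(y ~ 1, dat, id = "id", pedigree = sim$pedigree, ...)
  list(sim = sim, dat = dat, spec = spec)
}
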