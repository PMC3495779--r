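# Kernel mathematics, correlated-paternity decay, KinDist fitting,
# distance-distribution and circular tests.

test_that("kernel mean distances: closed forms vs quadrature", {
  expect_equal(kernel_mean_distance("exponential", a = 120), 240)
  expect_equal(kernel_mean_distance("normal", a = 100),
               100 * sqrt(pi) / 2)
  expect_equal(kernel_mean_distance("power_exponential", a = 100, b = 2),
               100 * gamma(3 / 2) / gamma(1))
  expect_error(kernel_mean_distance("geometric", a = 100, b = 2.5),
               "diverges")

  ## numerical cross-check: delta = int r^2 f / int r f for the
  ## power-exponential shape, several tail weights; substituting
  ## t = (r/a)^b turns the fat-tailed integrals into well-behaved ones
  for (b in c(0.3, 1, 2)) {
    a <- 50
    num <- integrate(function(t) a^3 / b * t^(3 / b - 1) * exp(-t),
                     0, Inf, rel.tol = 1e-10)$value
    den <- integrate(function(t) a^2 / b * t^(2 / b - 1) * exp(-t),
                     0, Inf, rel.tol = 1e-10)$value
    expect_equal(kernel_mean_distance("power_exponential", a, b),
                 num / den, tolerance = 1e-4)
  }
})

test_that("kernel densities integrate to 1 over the plane", {
  for (b in c(0.5, 1, 2, 3)) {
    tot <- integrate(function(r)
      2 * pi * r * kernel_density(r, "power_exponential", a = 80, b = b),
      0, Inf, rel.tol = 1e-8)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  tot_g <- integrate(function(r)
    2 * pi * r * kernel_density(r, "geometric", a = 60, b = 4.5),
    0, Inf, rel.tol = 1e-8)$value
  expect_equal(tot_g, 1, tolerance = 1e-6)
})

test_that("overlap integral matches direct enumeration over a male roster", {
  ## the fitted model predicts co-paternity as the normalised overlap of
  ## two pollen clouds; on a dense uniform roster the discrete
  ## probability that two mothers draw the same father reproduces it
  a <- 250 * gamma(2 / 0.5) / gamma(3 / 0.5); b <- 0.5
  sc <- sim_scenario(delta = 250, b = 0.5, n_males = 164, n_females = 29)
  ad <- simulate_adults(sc, seed = 3)
  males <- as.matrix(ad$ind[ad$ind$sex == "male", c("x", "y")])
  moms <- as.matrix(ad$ind[ad$ind$sex == "female", c("x", "y")])
  D <- pollenkin:::.pairwise_dist(moms, males)
  K <- exp(-(D / a)^b)
  P <- K / rowSums(K)
  Q <- P %*% t(P)
  Dm <- pollenkin:::.pairwise_dist(moms)
  ut <- upper.tri(Q)
  q0 <- mean(diag(Q))
  zb <- cut(Dm[ut], c(0, 100, 200, 300, 450, 700))
  obs <- tapply(Q[ut] / q0, zb, mean)
  zmid <- c(50, 150, 250, 375, 575)
  ov <- pollenkin:::.overlap_curve(zmid, "power_exponential", a, b, 250,
                                   256, 128)
  pred <- ov$Oz / ov$O0
  expect_lt(max(abs(obs - pred), na.rm = TRUE), 0.05)
})

test_that("correlated paternity limits: shared father vs disjoint pools", {
  ## two mothers fully sired by the same single male -> psi ~ 1
  sc <- sim_scenario(n_males = 1, n_females = 2, seeds_per_mother = 20,
                     m = 0, n_alleles = rep(8, 10), missing_rate = 0,
                     fecundity = "equal")
  dat <- sim_dataset(sc, seed = 5)
  ## reference frequencies from a broad population, not just one male
  ref <- attr(dat$adults, "gen_freqs")
  cv <- copaternity_curve(dat$progeny, dat$adults, freqs = ref)
  expect_gt(cv$pairs$psi[1], 0.7)
  expect_gt(cv$psi0, 0.7)

  ## immigrant-only pollen from a common outside pool, distance-free:
  ## between-mother psi fluctuates around a constant; the within-mother
  ## value equals it (no co-paternity signal beyond the pool itself)
  sc2 <- sim_scenario(n_males = 10, n_females = 10, seeds_per_mother = 20,
                      m = 1, n_alleles = rep(8, 10), missing_rate = 0)
  dat2 <- sim_dataset(sc2, seed = 6)
  cv2 <- copaternity_curve(dat2$progeny, dat2$adults)
  expect_lt(abs(mean(cv2$pairs$psi)), 0.06)
  expect_lt(abs(cv2$psi0 - mean(cv2$pairs$psi)), 0.06)
})

test_that("decay precheck: exact collinear case and simgen sign recovery", {
  cv <- structure(list(pairs = data.frame(
    mother_a = "a", mother_b = "b",
    distance = c(10, 50, 100, 300, 600),
    psi = 0.5 - 0.1 * log(c(10, 50, 100, 300, 600)), n_pairs = 10),
    psi0 = 0.6), class = "copat_curve")
  dt <- copaternity_decay_test(cv)
  expect_equal(dt$r, -1, tolerance = 1e-12)

  ## under the study-like scenario the decay is negative
  sc <- sim_scenario(delta = 250, b = 0.5, m = 0.7, n_males = 164,
                     n_females = 29, seeds_per_mother = 24)
  rs <- vapply(1:3, function(r) {
    dat <- sim_dataset(sc, seed = 200 + r)
    copaternity_decay_test(copaternity_curve(dat$progeny, dat$adults))$r
  }, 0)
  expect_true(all(rs < 0))
})

test_that("KinDist fit: scale equivariance and family selection", {
  ctrl <- list(n_r = 96, n_theta = 48, n_z = 20, n_starts = 4,
               maxit = 120)
  ## synthetic curve generated exactly from an exponential kernel
  set.seed(8)
  zs <- runif(120, 20, 900)
  a_true <- 125   # delta = 250
  ov <- pollenkin:::.overlap_curve(zs, "exponential", a_true, 1, 250,
                                   192, 96)
  psi0 <- 0.2
  psi <- psi0 * ov$Oz / ov$O0 + rnorm(120, 0, 0.002)
  cv <- structure(list(pairs = data.frame(
    mother_a = "a", mother_b = "b", distance = zs, psi = psi,
    n_pairs = 100), psi0 = psi0), class = "copat_curve")
  fits <- lapply(c("exponential", "normal", "geometric",
                   "power_exponential"), function(fam)
    suppressWarnings(fit_dispersal_kernel(cv, fam, control = ctrl)))
  names(fits) <- c("exponential", "normal", "geometric",
                   "power_exponential")
  rss <- vapply(fits, `[[`, 0, "rss")
  ## the exponential truth beats normal and geometric; the
  ## power-exponential family nests it so may tie within tolerance
  expect_lt(rss[["exponential"]], rss[["normal"]])
  expect_lt(rss[["exponential"]], rss[["geometric"]] + 1e-6)
  expect_lt(abs(fits$exponential$delta - 250) / 250, 0.15)

  ## doubling all distances doubles the fitted mean distance
  cv2 <- cv
  cv2$pairs$distance <- cv2$pairs$distance * 2
  f1 <- suppressWarnings(fit_dispersal_kernel(cv, "exponential",
                                              control = ctrl))
  f2 <- suppressWarnings(fit_dispersal_kernel(cv2, "exponential",
                                              control = ctrl))
  expect_equal(f2$delta / f1$delta, 2, tolerance = 0.05)
})

test_that("observed vs potential mating distances: counts and extremes", {
  sc <- sim_scenario(n_males = 164, n_females = 29)
  ad <- simulate_adults(sc, seed = 2)
  res <- mating_distance_test(runif(50, 0, 500), ad)
  expect_equal(res$n_potential, 164 * 29)

  males <- as.matrix(ad$ind[ad$ind$sex == "male", c("x", "y")])
  moms <- as.matrix(ad$ind[ad$ind$sex == "female", c("x", "y")])
  pot <- sort(as.numeric(pollenkin:::.pairwise_dist(males, moms)))
  short <- pot[seq_len(length(pot) %/% 10)]
  res2 <- mating_distance_test(short, ad)
  expect_gt(res2$d, 0.5)
  expect_lt(res2$p, 1e-3)
})

test_that("permutation p of the distance test is calibrated", {
  sc <- sim_scenario(n_males = 40, n_females = 8)
  ad <- simulate_adults(sc, seed = 13)
  males <- as.matrix(ad$ind[ad$ind$sex == "male", c("x", "y")])
  moms <- as.matrix(ad$ind[ad$ind$sex == "female", c("x", "y")])
  pot <- as.numeric(pollenkin:::.pairwise_dist(males, moms))
  set.seed(4)
  rej <- mean(replicate(120, {
    obs <- sample(pot, 40)
    mating_distance_test(obs, ad, n_perm = 99)$p_perm < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("Watson U2: degenerate inputs, calibration and power", {
  set.seed(6)
  a <- runif(100, 0, 360)
  same <- watson_u2_test(a, a)
  expect_equal(same$u2, 0)
  expect_equal(same$p, 1)
  expect_error(watson_u2_test(a[1:5], a), "at least 8")
  expect_error(watson_u2_test(rep(10, 20), rep(10, 20)), "identical")

  rwn <- function(n, mu, sd) (mu + rnorm(n, 0, sd)) %% 360
  rej <- mean(replicate(200,
    watson_u2_test(rwn(80, 120, 50), rwn(80, 120, 50))$p < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)

  ## 90 degree separation detected decisively
  pw <- watson_u2_test(rwn(200, 90, 40), rwn(200, 180, 40))
  expect_lt(pw$p, 1e-3)
  ## permutation p agrees with the asymptotic one
  w2 <- watson_u2_test(rwn(40, 0, 70), rwn(40, 60, 70), n_perm = 500,
                       seed = 2)
  expect_lt(abs(w2$p - w2$p_perm), 0.08)
})

test_that("rose histograms partition the sample", {
  b <- c(0, 11, 11.4, 90, 180, 270, 355)
  r <- rose_counts(b, n_sectors = 16)
  expect_equal(sum(r$counts), length(b))
  expect_equal(length(r$counts), 16)
  ## 355 and 0 fall in the north sector (centred on 0)
  expect_gte(r$counts[1], 2)
})
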