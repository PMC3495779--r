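# LOD machinery, threshold calibration, assignment, immigration bounds
# and the mating network.

test_that("Mendelian transition probabilities", {
  expect_equal(transition_probability(c("A", "B"), c("A", "A"),
                                      c("B", "B")), 1)
  expect_equal(transition_probability(c("A", "A"), c("A", "B"),
                                      c("A", "B")), 0.25)
  ## normalisation: offspring genotypes sum to 1 for any parent pair
  mo <- c("A", "B"); fa <- c("B", "C")
  offs <- list(c("A", "B"), c("A", "C"), c("B", "B"), c("B", "C"))
  expect_equal(sum(vapply(offs, transition_probability, 0,
                          mother = mo, father = fa)), 1)
})

test_that("LOD scores agree with exhaustive enumeration on a 2-locus toy", {
  ad <- tiny_adults()
  df <- data.frame(seed_id = "s1", mother_id = "F1",
                   LocA = "140/142", LocB = "99/99",
                   stringsAsFactors = FALSE)
  pr <- make_progeny(df, ad)
  freqs <- list(LocA = c("140" = 0.4, "142" = 0.35, "148" = 0.25),
                LocB = c("95" = 0.3, "99" = 0.5, "101" = 0.2))
  lt <- lod_scores(pr, ad, freqs, freq_floor = 0)

  ## independent oracle: numerator from transition probabilities,
  ## denominator by enumerating every paternal allele
  oracle <- function(seed, mother, father) {
    total <- 0
    for (l in names(freqs)) {
      s <- seed[[l]]; m <- mother[[l]]; f <- father[[l]]
      num <- transition_probability(s, m, f)
      den <- 0
      for (x in names(freqs[[l]]))
        den <- den + freqs[[l]][[x]] *
          sum(vapply(1:2, function(i)
            0.5 * identical(sort(s), sort(c(m[i], x))), 0))
      total <- total + log(num) - log(den)
    }
    total
  }
  seed <- list(LocA = c("140", "142"), LocB = c("99", "99"))
  mother <- list(LocA = c("140", "140"), LocB = c("99", "101"))
  m1 <- list(LocA = c("140", "142"), LocB = c("95", "95"))
  m2 <- list(LocA = c("142", "148"), LocB = c("95", "99"))
  expect_equal(lt$LOD["s1", "M1"], oracle(seed, mother, m1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(lt$LOD["s1", "M2"], oracle(seed, mother, m2),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## the single-pair interface agrees with the table engine
  expect_equal(lod_score(seed, mother, m2, freqs),
               unname(lt$LOD["s1", "M2"]), tolerance = 1e-12)
})

test_that("monomorphic loci are uninformative: LOD = 0", {
  ind <- data.frame(id = c("M1", "F1"), sex = c("male", "female"),
                    x = c(0, 10), y = c(0, 0))
  geno <- array("7", c(2, 2, 3),
                dimnames = list(NULL, NULL, c("L1", "L2", "L3")))
  ad <- spatial_genotypes(ind, geno)
  df <- data.frame(seed_id = "s1", mother_id = "F1",
                   L1 = "7/7", L2 = "7/7", L3 = "7/7",
                   stringsAsFactors = FALSE)
  pr <- make_progeny(df, ad)
  lt <- lod_scores(pr, ad, list(L1 = c("7" = 1), L2 = c("7" = 1),
                                L3 = c("7" = 1)), freq_floor = 0)
  expect_equal(unname(lt$LOD["s1", "M1"]), 0)
})

test_that("true fathers score positive LOD with informative markers", {
  sc <- sim_scenario(n_males = 50, n_females = 10, seeds_per_mother = 20,
                     m = 0, n_alleles = rep(10, 7), missing_rate = 0,
                     F = 0, fecundity = "equal")
  dat <- sim_dataset(sc, seed = 14)
  ppf <- paternal_pool_freqs(dat$progeny, dat$adults)
  lt <- lod_scores(dat$progeny, dat$adults, ppf)
  true_lod <- lt$LOD[cbind(seq_len(nrow(dat$truth$fathers)),
                           match(dat$truth$fathers$father_id, lt$males))]
  expect_gt(mean(true_lod > 0), 0.95)
})

test_that("threshold calibration is stable and handles degenerate markers", {
  sc <- sim_scenario(n_males = 60, n_females = 12, missing_rate = 0)
  ad <- simulate_adults(sc, seed = 21)
  dat <- sim_dataset(sc, seed = 21)
  ppf <- paternal_pool_freqs(dat$progeny, ad)
  tfs <- vapply(1:3, function(s)
    calibrate_lod_threshold(ad, ppf, F = 0.152, n_sim = 4000,
                            seed = s)$TF, 0)
  expect_lt(max(tfs) - min(tfs), 1.5)

  ## two weak biallelic loci: finite threshold with a warning of poor
  ## separation is acceptable behaviour
  sc2 <- sim_scenario(n_males = 30, n_females = 8, n_alleles = c(2, 2),
                      missing_rate = 0)
  ad2 <- simulate_adults(sc2, seed = 3)
  af2 <- allele_freqs(ad2)
  tf2 <- suppressWarnings(
    calibrate_lod_threshold(ad2, af2, n_sim = 2000, seed = 1))
  expect_true(is.finite(tf2$TF))

  ## highly informative markers: inside-father LODs dominate and the
  ## distributions barely overlap
  sc3 <- sim_scenario(n_males = 40, n_females = 8,
                      n_alleles = rep(20, 12), missing_rate = 0)
  ad3 <- simulate_adults(sc3, seed = 4)
  af3 <- allele_freqs(ad3)
  tf3 <- suppressWarnings(
    calibrate_lod_threshold(ad3, af3, n_sim = 2000, seed = 2))
  if (length(tf3$best_random) > 50) {
    ov <- mean(tf3$best_inside < quantile(tf3$best_random, 0.99))
    expect_lt(ov, 0.01)
  } else {
    expect_gt(min(tf3$best_inside), max(c(tf3$best_random, 0)))
  }
})

test_that("assignment: categories partition, ties break by distance, TF monotone", {
  sc <- sim_scenario(n_males = 60, n_females = 12, seeds_per_mother = 20,
                     m = 0.4, missing_rate = 0.02)
  dat <- sim_dataset(sc, seed = 33)
  ppf <- paternal_pool_freqs(dat$progeny, dat$adults)
  thr <- suppressWarnings(
    calibrate_lod_threshold(dat$adults, ppf, F = 0.152, n_sim = 3000,
                            seed = 1))
  pa <- assign_paternity(dat$progeny, dat$adults, thr$TF, ppf, F = 0.152)
  cats <- pa$seeds$category[pa$seeds$analysed]
  expect_false(anyNA(cats))
  expect_equal(sum(pa$counts), pa$n_analysed)

  ## raising TF never moves a seed from below-threshold to assigned
  pa_hi <- assign_paternity(dat$progeny, dat$adults, thr$TF + 2, ppf,
                            F = 0.152)
  was_below <- pa$seeds$category == "compatible_below_TF"
  expect_false(any(pa_hi$seeds$category[was_below] == "assigned",
                   na.rm = TRUE))
  ## and category (i) seeds stay category (i)
  was_none <- pa$seeds$category == "no_compatible_father"
  expect_true(all(pa_hi$seeds$category[was_none] == "no_compatible_father",
                  na.rm = TRUE))

  ## tie-break: two compatible males above TF, the closer one wins
  ind <- data.frame(id = c("Mnear", "Mfar", "F1"),
                    sex = c("male", "male", "female"),
                    x = c(10, 500, 0), y = c(0, 0, 0))
  geno <- array(NA_character_, c(3, 2, 5),
                dimnames = list(NULL, NULL, paste0("L", 1:5)))
  for (l in 1:5) geno[, , l] <- rbind(c("1", "2"), c("1", "2"),
                                      c("3", "3"))
  adt <- spatial_genotypes(ind, geno)
  dft <- data.frame(seed_id = "s1", mother_id = "F1",
                    L1 = "1/3", L2 = "1/3", L3 = "1/3", L4 = "1/3",
                    L5 = "1/3", stringsAsFactors = FALSE)
  prt <- make_progeny(dft, adt, min_loci = 5)
  fq <- setNames(rep(list(c("1" = 0.2, "2" = 0.4, "3" = 0.4)), 5),
                 paste0("L", 1:5))
  pat <- assign_paternity(prt, adt, TF = 0.1, fq)
  expect_equal(pat$seeds$father_id[1], "Mnear")
  expect_equal(pat$seeds$distance[1], 10)
  expect_equal(pat$seeds$bearing[1], 270)  # father east of mother
})

test_that("immigration bounds arithmetic and degenerate cases", {
  fake <- structure(list(counts = c(no_compatible_father = 506,
                                    compatible_below_TF = 63,
                                    assigned = 121),
                         n_analysed = 690), class = "paternity_result")
  ib <- immigration_bounds(fake)
  expect_equal(unname(round(100 * ib, 1)), c(73.3, 82.5), tolerance = 0.1)

  all_assigned <- structure(list(counts = c(no_compatible_father = 0,
                                            compatible_below_TF = 0,
                                            assigned = 50),
                                 n_analysed = 50),
                            class = "paternity_result")
  expect_equal(unname(immigration_bounds(all_assigned)), c(0, 0))
})

test_that("mating network: conservation, distances, per-male counts", {
  sc <- sim_scenario(n_males = 50, n_females = 10, seeds_per_mother = 20,
                     m = 0, n_alleles = rep(10, 7), missing_rate = 0,
                     F = 0, fecundity = "equal", delta = 250)
  dat <- sim_dataset(sc, seed = 17)
  ppf <- paternal_pool_freqs(dat$progeny, dat$adults)
  thr <- suppressWarnings(
    calibrate_lod_threshold(dat$adults, ppf, n_sim = 2000, seed = 3))
  pa <- assign_paternity(dat$progeny, dat$adults, thr$TF, ppf)
  net <- mating_network(pa, dat$adults)
  expect_equal(sum(net$sired_counts), pa$counts[["assigned"]],
               ignore_attr = TRUE)
  expect_equal(sum(net$edges$n_seeds), pa$counts[["assigned"]],
               ignore_attr = TRUE)
  ## network mean distance within 20% of the realized kernel distances
  truth_mean <- mean(dat$truth$fathers$distance, na.rm = TRUE)
  expect_lt(abs(net$summary$mean - truth_mean) / truth_mean, 0.2)

  ## single assigned seed: one edge with the Euclidean distance
  one <- pa$seeds[pa$seeds$category == "assigned", ][1, ]
  fake <- structure(list(seeds = cbind(one, row.names = NULL),
                         counts = c(no_compatible_father = 0,
                                    compatible_below_TF = 0, assigned = 1),
                         n_analysed = 1, males = pa$males),
                    class = "paternity_result")
  net1 <- mating_network(fake, dat$adults)
  expect_equal(nrow(net1$edges), 1)
  xyf <- dat$adults$ind[match(one$father_id, dat$adults$ind$id),
                        c("x", "y")]
  xym <- dat$adults$ind[match(one$mother_id, dat$adults$ind$id),
                        c("x", "y")]
  expect_equal(net1$edges$distance,
               sqrt(sum((xyf - xym)^2)), tolerance = 1e-9)
})

test_that("assignment accuracy improves with more loci", {
  base <- sim_scenario(n_males = 50, n_females = 10, seeds_per_mother = 20,
                       m = 0, n_alleles = rep(8, 10), missing_rate = 0,
                       F = 0, fecundity = "equal")
  dat <- sim_dataset(base, seed = 55)
  acc_for <- function(n_loci) {
    keep <- dimnames(dat$progeny$geno)[[3]][seq_len(n_loci)]
    sub_pr <- progeny_array(dat$progeny$seeds[c("seed_id", "mother_id")],
                            dat$progeny$geno[, , keep, drop = FALSE],
                            dat$adults, min_loci = min(5, n_loci))
    sub_ad <- spatial_genotypes(dat$adults$ind,
                                dat$adults$geno[, , keep, drop = FALSE])
    ppf <- paternal_pool_freqs(sub_pr, sub_ad)
    thr <- suppressWarnings(
      calibrate_lod_threshold(sub_ad, ppf, n_sim = 2000, seed = 2))
    pa <- assign_paternity(sub_pr, sub_ad, thr$TF, ppf)
    ok <- pa$seeds$category == "assigned"
    sum(pa$seeds$father_id[ok] == dat$truth$fathers$father_id[ok]) /
      pa$n_analysed
  }
  expect_gt(acc_for(10), acc_for(5) - 0.02)
})
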