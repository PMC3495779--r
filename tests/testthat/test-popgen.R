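# Allele frequencies, paternal-pool inference, diversity, HWE exact
# test, null alleles and exclusion probabilities.

test_that("gene-count allele frequencies and edge cases", {
  ind <- data.frame(id = c("a", "b"), sex = c("male", "female"),
                    x = 0:1, y = 0:1)
  geno <- array(NA_character_, c(2, 2, 2),
                dimnames = list(NULL, NULL, c("L1", "L2")))
  geno[, , 1] <- rbind(c("A", "A"), c("A", "B"))
  geno[, , 2] <- rbind(c("C", "C"), c("C", "C"))
  x <- spatial_genotypes(ind, geno)
  af <- allele_freqs(x)
  expect_equal(unname(af$freqs$L1), c(0.75, 0.25))
  expect_equal(unname(af$freqs$L2), 1)            # monomorphic
  ## locus with no data errors
  geno2 <- geno; geno2[, , 2] <- NA_character_
  expect_error(allele_freqs(spatial_genotypes(ind, geno2)), "L2")
  ## simgen output matches the generative frequencies within
  ## binomial sampling error (3 SE)
  sc <- sim_scenario(n_males = 1500, n_females = 100,
                     n_alleles = c(6, 10), missing_rate = 0, F = 0)
  ad <- simulate_adults(sc, seed = 4)
  gen <- attr(ad, "gen_freqs")
  est <- allele_freqs(ad)
  for (l in names(gen)) {
    p <- gen[[l]][names(est$freqs[[l]])]
    se <- sqrt(p * (1 - p) / est$n_genes[l])
    expect_true(all(abs(est$freqs[[l]] - p) < 3 * se + 1e-3), label = l)
  }
})

test_that("paternal gametes by maternal subtraction use Mendelian weights", {
  ad <- tiny_adults()  # F1 is 140/140 at LocA, 99/101 at LocB
  df <- data.frame(seed_id = c("s1", "s2", "s3"), mother_id = "F1",
                   LocA = c("140/142", "140/140", "148/148"),
                   LocB = c("99/101", "99/99", "95/101"),
                   stringsAsFactors = FALSE)
  pr <- make_progeny(df, ad)
  pg <- suppressWarnings(paternal_gametes(pr, ad))
  ## unambiguous: seed 140/142 from mother 140/140 -> paternal 142
  expect_equal(pg$W$LocA["s1", "142"], 1)
  ## mother heterozygous 99/101, seed 99/101 -> each weight 0.5
  expect_equal(pg$W$LocB["s1", "99"], 0.5)
  expect_equal(pg$W$LocB["s1", "101"], 0.5)
  ## seed 99/99 from mother 99/101 -> paternal 99
  expect_equal(pg$W$LocB["s2", "99"], 1)
  ## incompatibility: seed 148/148 cannot come from mother 140/140
  expect_true(any(pg$incompatible$seed_id == "s3" &
                  pg$incompatible$locus == "LocA"))
  expect_false(pg$typed["s3", "LocA"])

  ## with no immigration the paternal pool matches the male population
  sc <- sim_scenario(n_males = 60, n_females = 12, seeds_per_mother = 25,
                     m = 0, n_alleles = rep(8, 5), missing_rate = 0, F = 0,
                     fecundity = "equal")
  dat <- sim_dataset(sc, seed = 8)
  ppf <- paternal_pool_freqs(dat$progeny, dat$adults)
  mf <- allele_freqs(dat$adults, subset = "male")
  for (l in names(ppf$freqs)) {
    u <- union(names(ppf$freqs[[l]]), names(mf$freqs[[l]]))
    a <- setNames(rep(0, length(u)), u); b <- a
    a[names(ppf$freqs[[l]])] <- ppf$freqs[[l]]
    b[names(mf$freqs[[l]])] <- mf$freqs[[l]]
    expect_lt(max(abs(a - b)), 0.12)
  }
})

test_that("diversity summary: aggregation rules and sign checks", {
  ## overall A is the sum and He the unweighted mean of per-locus values,
  ## as in the published summary table layout: applying the package's
  ## aggregation to the printed per-locus columns reproduces the
  ## printed overall values
  A <- c(14, 6, 18, 10, 15, 3, 3)
  He <- c(0.820, 0.704, 0.883, 0.774, 0.779, 0.432, 0.212)
  expect_equal(sum(A), 69)
  expect_equal(round(mean(He), 3), 0.658)

  ## all-heterozygote sample has negative f
  ind <- data.frame(id = letters[1:4], sex = rep(c("male", "female"), 2),
                    x = 1:4, y = 1:4)
  geno <- array(NA_character_, c(4, 2, 1),
                dimnames = list(NULL, NULL, "L1"))
  geno[, , 1] <- rbind(c("A", "B"), c("A", "B"), c("A", "B"), c("A", "B"))
  d <- genetic_diversity(spatial_genotypes(ind, geno), hwe = FALSE,
                         null_alleles = FALSE, exclusion = FALSE)
  expect_lt(d$f[1], 0)

  ## He and f invariant under allele relabelling
  sc <- sim_scenario(n_males = 80, n_females = 20, n_alleles = c(5, 7),
                     missing_rate = 0)
  ad <- simulate_adults(sc, seed = 2)
  ad2 <- ad
  for (l in seq_len(dim(ad2$geno)[3])) {
    labs <- sort(unique(c(ad2$geno[, , l])))
    relab <- setNames(paste0("z", rev(seq_along(labs))), labs)
    ad2$geno[, , l] <- relab[ad2$geno[, , l]]
  }
  ad2 <- spatial_genotypes(ad2$ind, ad2$geno)
  d1 <- genetic_diversity(ad, hwe = FALSE, null_alleles = FALSE,
                          exclusion = FALSE)
  d2 <- genetic_diversity(ad2, hwe = FALSE, null_alleles = FALSE,
                          exclusion = FALSE)
  expect_equal(d1$He, d2$He, tolerance = 1e-12)
  expect_equal(d1$f, d2$f, tolerance = 1e-12)
})

test_that("Markov-chain HWE test matches full enumeration and has power", {
  ## biallelic table small enough for exact enumeration
  set.seed(31)
  g <- cbind(sample(2, 60, TRUE, c(0.6, 0.4)),
             sample(2, 60, TRUE, c(0.6, 0.4)))
  n11 <- sum(g[, 1] == 1 & g[, 2] == 1)
  n22 <- sum(g[, 1] == 2 & g[, 2] == 2)
  n12 <- 60 - n11 - n22
  p_exact <- hwe_exact_biallelic(n11, n12, n22)
  mc <- hwe_exact_test(g, dememorization = 2000, batches = 20,
                       iter_per_batch = 2000, seed = 5)
  expect_lt(abs(mc$p - p_exact), 3 * mc$se + 0.02)

  ## strong heterozygote deficit is detected
  gd <- cbind(c(rep(1, 140), rep(2, 60)), c(rep(1, 140), rep(2, 60)))
  ## shuffle a few to avoid the degenerate all-homozygote table
  gd[1:10, 2] <- 3 - gd[1:10, 1]
  mcd <- hwe_exact_test(gd, dememorization = 2000, batches = 10,
                        iter_per_batch = 1000, seed = 5)
  expect_lt(mcd$p, 0.01)

  ## monomorphic locus: defined p = 1
  gm <- cbind(rep(1L, 30), rep(1L, 30))
  expect_equal(hwe_exact_test(gm)$p, 1)
})

test_that("HWE test is calibrated under the null", {
  set.seed(77)
  rej <- mean(replicate(150, {
    g <- cbind(sample(3, 80, TRUE, c(0.5, 0.3, 0.2)),
               sample(3, 80, TRUE, c(0.5, 0.3, 0.2)))
    hwe_exact_test(g, dememorization = 500, batches = 5,
                   iter_per_batch = 400)$p < 0.05
  }))
  ## binomial 3 SE band around 0.05 for 150 replicates (exact test is
  ## conservative on discrete tables, so only the upper side is tight)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("null-allele EM: zero without excess, recovery, boundary", {
  set.seed(12)
  g <- cbind(sample(4, 400, TRUE), sample(4, 400, TRUE))
  expect_lt(null_allele_freq(g), 0.02)

  ## true null allele at 0.15 hiding as apparent homozygotes
  pv <- c(0.25, 0.2, 0.2, 0.2, 0.15)     # allele 5 is the null
  g1 <- sample(5, 700, TRUE, pv); g2 <- sample(5, 700, TRUE, pv)
  vis <- !(g1 == 5 & g2 == 5)
  a1 <- ifelse(g1[vis] == 5, g2[vis], g1[vis])
  a2 <- ifelse(g2[vis] == 5, g1[vis], g2[vis])
  obs <- cbind(a1, ifelse(g1[vis] == 5 | g2[vis] == 5, a1, a2))
  est <- null_allele_freq(obs)
  expect_lt(abs(est - 0.15), 0.05)

  ## complete homozygosity at a biallelic locus: estimate at the upper
  ## end of the EM support
  gh <- cbind(rep(1:2, c(50, 50)), rep(1:2, c(50, 50)))
  expect_gt(null_allele_freq(gh), 0.3)
})

test_that("exclusion probabilities: enumeration, oracle, combination", {
  ## monomorphic locus excludes nothing
  expect_equal(exclusion_probability(list(L = c(a = 1)))$per_locus[[1]], 0)

  ## three equifrequent alleles: compare with a Monte-Carlo oracle over
  ## simulated mother/offspring/non-father triplets
  p <- setNames(rep(1 / 3, 3), c("1", "2", "3"))
  E <- exclusion_probability(list(L = p))$per_locus[[1]]
  set.seed(99)
  n <- 4e4
  M <- cbind(sample(3, n, TRUE), sample(3, n, TRUE))
  Fa <- cbind(sample(3, n, TRUE), sample(3, n, TRUE))
  NF <- cbind(sample(3, n, TRUE), sample(3, n, TRUE))
  mat <- M[cbind(1:n, sample(2, n, TRUE))]
  pat <- Fa[cbind(1:n, sample(2, n, TRUE))]
  excl <- vapply(1:n, function(i) {
    o <- c(mat[i], pat[i]); S <- integer(0)
    if (o[1] %in% M[i, ]) S <- c(S, o[2])
    if (o[2] %in% M[i, ]) S <- c(S, o[1])
    S <- unique(S)
    !(NF[i, 1] %in% S) && !(NF[i, 2] %in% S)
  }, TRUE)
  se <- sd(excl) / sqrt(n)
  expect_lt(abs(E - mean(excl)), 3 * se)

  ## combining is monotone non-decreasing in the number of loci
  per <- c(0.4, 0.3, 0.2)
  cums <- vapply(1:3, function(k) combined_exclusion(per[1:k]), 0)
  expect_true(all(diff(cums) >= 0))
})
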