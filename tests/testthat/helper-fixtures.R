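# Shared fixture builders: tiny hand-written tables and study-like
# simulation scenarios. All randomness is seeded by the caller.

## three adults, two loci, hand-written
tiny_adults <- function() {
  ind <- data.frame(
    id = c("M1", "M2", "F1"),
    sex = c("male", "male", "female"),
    x = c(0, 100, 50), y = c(0, 0, 80),
    habitat = c("hedge", "canopy", "shrubland"),
    stringsAsFactors = FALSE)
  geno <- array(NA_character_, c(3, 2, 2),
                dimnames = list(NULL, NULL, c("LocA", "LocB")))
  geno[, , 1] <- rbind(c("140", "142"), c("142", "148"), c("140", "140"))
  geno[, , 2] <- rbind(c("95", "95"), c("95", "99"), c("99", "101"))
  spatial_genotypes(ind, geno)
}

## build a progeny array from a data.frame of "a/b" locus columns
make_progeny <- function(df, adults, min_loci = 1L) {
  locus_cols <- setdiff(names(df), c("seed_id", "mother_id"))
  n <- nrow(df)
  geno <- array(NA_character_, c(n, 2L, length(locus_cols)),
                dimnames = list(df$seed_id, NULL, locus_cols))
  for (l in seq_along(locus_cols)) {
    parts <- strsplit(df[[locus_cols[l]]], "/", fixed = TRUE)
    m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    m[m == "NA"] <- NA_character_
    geno[, , l] <- m
  }
  progeny_array(df[c("seed_id", "mother_id")], geno, adults,
                min_loci = min_loci)
}

## study-like scenario (conditions the generator defaults emulate),
## optionally overridden
study_scenario <- function(...) {
  sim_scenario(...)
}

## quick simulated data set
sim_dataset <- function(scenario, seed) {
  adults <- simulate_adults(scenario, seed = seed)
  mat <- simulate_mating(adults, scenario, seed = seed)
  list(adults = adults, progeny = mat$progeny, truth = mat$truth)
}

## independent transcription of the Loiselle kinship estimator used as
## an oracle: explicit loops, individual allele frequencies 0/0.5/1,
## correction p(1-p)/(n_genes - 1), multilocus ratio of sums
loiselle_oracle <- function(geno_list, freqs) {
  n <- nrow(geno_list[[1]])
  Fm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (l in seq_along(geno_list)) {
        g <- geno_list[[l]]
        p <- freqs[[l]]
        if (anyNA(g[i, ]) || anyNA(g[j, ])) next
        ng <- 2 * sum(!is.na(g[, 1]))
        D <- 0
        for (a in names(p)) D <- D + p[[a]] * (1 - p[[a]])
        if (D <= 0) next
        for (a in names(p)) {
          pia <- mean(g[i, ] == a)
          pja <- mean(g[j, ] == a)
          num <- num + (pia - p[[a]]) * (pja - p[[a]]) +
            p[[a]] * (1 - p[[a]]) / (ng - 1)
        }
        den <- den + D
      }
      Fm[i, j] <- Fm[j, i] <- num / den
    }
  }
  Fm
}

## exact Hardy-Weinberg probability test for a biallelic sample by full
## enumeration over heterozygote counts (Levene's conditional law)
hwe_exact_biallelic <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  logp <- function(h) {
    stopifnot((n1 - h) %% 2 == 0)
    a <- (n1 - h) / 2
    b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(n1) + lfactorial(2 * n - n1) -
      lfactorial(2 * n)
  }
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  lp <- vapply(hs, logp, 0)
  p_all <- exp(lp - max(lp)); p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n12, hs)]
  sum(p_all[p_all <= p_obs + 1e-12])
}
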