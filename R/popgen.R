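# Allele frequencies, paternal-pool frequencies by maternal subtraction,
# diversity statistics, Hardy-Weinberg exact test, null-allele estimation
# and paternity-exclusion probabilities.

#' Gene-count allele frequencies
#'
#' @param x a [spatial_genotypes] or [progeny_array] object.
#' @param subset optional: `"male"`, `"female"`, or a character vector of
#'   individual ids to restrict the sample.
#' @return An object of class `allele_freqs`: list with `freqs` (named
#'   list per locus of named frequency vectors) and `n_genes` (typed gene
#'   copies per locus).
#' @export
allele_freqs <- function(x, subset = NULL) {
  geno <- x$geno
  if (!is.null(subset) && inherits(x, "spatial_genotypes")) {
    keep <- if (all(subset %in% c("male", "female")))
      x$ind$sex %in% subset else x$ind$id %in% subset
    geno <- geno[keep, , , drop = FALSE]
  }
  loci <- dimnames(geno)[[3]]
  freqs <- vector("list", length(loci))
  n_genes <- integer(length(loci))
  for (l in seq_along(loci)) {
    a <- c(geno[, , l])
    a <- a[!is.na(a)]
    if (!length(a))
      stop("locus ", loci[l], " has no typed genotypes")
    tab <- table(factor(a, levels = .sort_alleles(a)))
    n_genes[l] <- sum(tab)
    freqs[[l]] <- as.numeric(tab) / sum(tab)
    names(freqs[[l]]) <- names(tab)
  }
  names(freqs) <- loci
  names(n_genes) <- loci
  structure(list(freqs = freqs, n_genes = n_genes), class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("Allele frequencies for %d loci (%s alleles; %s gene copies)\n",
              length(x$freqs),
              paste(range(lengths(x$freqs)), collapse = "-"),
              paste(range(x$n_genes), collapse = "-")))
  invisible(x)
}

# ---- paternal gamete inference ------------------------------------------

#' Infer paternal gametes by maternal subtraction
#'
#' For each seed and locus the paternal allele is obtained by subtracting
#' the maternal contribution from the seed genotype. When both seed
#' alleles occur in the mother the paternal allele is ambiguous and each
#' compatible allele receives a fractional weight proportional to the
#' Mendelian probability that the mother transmitted the other one.
#' Seed/mother incompatibilities are flagged and the locus skipped for
#' that seed.
#'
#' @param progeny a [progeny_array].
#' @param adults the [spatial_genotypes] table containing the mothers.
#' @return Object of class `paternal_gametes`: list with `W` (per locus,
#'   an `n_seeds x n_alleles` matrix of paternal-allele weights, rows
#'   summing to 1 for typed compatible seed-loci and 0 otherwise),
#'   `catalog` (allele labels per locus), `typed` (seeds x loci logical),
#'   `incompatible` (data.frame of flagged seed/locus pairs) and `seeds`.
#' @export
paternal_gametes <- function(progeny, adults) {
  stopifnot(inherits(progeny, "progeny_array"),
            inherits(adults, "spatial_genotypes"))
  loci <- dimnames(progeny$geno)[[3]]
  catalog <- .union_catalog(adults$loci, progeny$loci)[loci]
  sc <- .codes(progeny$geno, catalog)
  ac <- .codes(adults$geno, catalog)
  midx <- match(progeny$seeds$mother_id, adults$ind$id)
  if (anyNA(midx))
    stop("seeds with mothers absent from the adult table: ",
         paste(unique(progeny$seeds$mother_id[is.na(midx)]), collapse = ", "))
  n <- nrow(progeny$seeds)
  W <- vector("list", length(loci))
  typed <- matrix(FALSE, n, length(loci),
                  dimnames = list(progeny$seeds$seed_id, loci))
  bad <- list()
  for (l in seq_along(loci)) {
    k <- length(catalog[[l]])
    w <- matrix(0, n, k, dimnames = list(progeny$seeds$seed_id, catalog[[l]]))
    s1 <- sc[[l]][, 1]; s2 <- sc[[l]][, 2]
    m1 <- ac[[l]][midx, 1]; m2 <- ac[[l]][midx, 2]
    ok <- !is.na(s1) & !is.na(m1)
    for (i in which(ok)) {
      a <- s1[i]; b <- s2[i]
      pm <- function(x) 0.5 * ((x == m1[i]) + (x == m2[i]))
      if (a == b) {
        w[i, a] <- pm(a)
      } else {
        w[i, a] <- pm(b)
        w[i, b] <- pm(a)
      }
      tot <- sum(w[i, ])
      if (tot > 0) {
        w[i, ] <- w[i, ] / tot
        typed[i, l] <- TRUE
      } else {
        w[i, ] <- 0
        bad[[length(bad) + 1L]] <- data.frame(
          seed_id = progeny$seeds$seed_id[i], locus = loci[l],
          stringsAsFactors = FALSE)
      }
    }
    W[[l]] <- w
  }
  names(W) <- loci
  incompatible <- if (length(bad)) do.call(rbind, bad) else
    data.frame(seed_id = character(), locus = character())
  if (nrow(incompatible))
    warning(nrow(incompatible),
            " seed/mother incompatibilities flagged; loci skipped for those seeds")
  structure(list(W = W, catalog = catalog, typed = typed,
                 incompatible = incompatible, seeds = progeny$seeds),
            class = "paternal_gametes")
}

#' Paternal-pool allele frequencies
#'
#' Reference allele frequencies of the effective pollen cloud, obtained
#' by maternal subtraction over all seeds: each seed contributes its
#' inferred paternal gamete (fractional weights for ambiguous cases).
#'
#' @param progeny a [progeny_array] (or a precomputed [paternal_gametes]
#'   object).
#' @param adults the [spatial_genotypes] table with the mothers; ignored
#'   when `progeny` is already a `paternal_gametes` object.
#' @return An `allele_freqs` object (gene counts are summed gamete
#'   weights, rounded for reporting).
#' @export
paternal_pool_freqs <- function(progeny, adults = NULL) {
  pg <- if (inherits(progeny, "paternal_gametes")) progeny else
    paternal_gametes(progeny, adults)
  freqs <- lapply(pg$W, function(w) {
    cs <- colSums(w)
    if (sum(cs) == 0) stop("no informative paternal gametes at a locus")
    cs / sum(cs)
  })
  n_genes <- vapply(pg$W, function(w) sum(rowSums(w) > 0), 0)
  structure(list(freqs = freqs, n_genes = round(n_genes)),
            class = "allele_freqs")
}

# ---- diversity summary ---------------------------------------------------

## Weir & Cockerham (1984) variance components for a single sample:
## per locus and allele, b = between-individual and c = within-individual
## components; f = 1 - sum(c) / sum(b + c)
.wc_components <- function(codes) {
  ok <- !is.na(codes[, 1])
  g <- codes[ok, , drop = FALSE]
  n <- nrow(g)
  if (n < 2) return(NULL)
  k <- max(g)
  bs <- cs <- numeric(k)
  for (a in seq_len(k)) {
    cnt <- (g[, 1] == a) + (g[, 2] == a)
    p <- mean(cnt) / 2
    H <- mean(cnt == 1L)
    bs[a] <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * H)
    cs[a] <- H / 2
  }
  list(b = bs, c = cs)
}

#' Genetic diversity summary per locus
#'
#' Computes, per locus and overall: number of alleles (A), Nei's unbiased
#' expected heterozygosity (He), the Weir-Cockerham inbreeding
#' coefficient (f), a Markov-chain exact Hardy-Weinberg p-value, the
#' EM-estimated null-allele frequency, and the known-mother paternity
#' exclusion probability. The overall row uses A summed over loci, He as
#' the unweighted mean, f as the multilocus Weir-Cockerham estimator
#' (variance components summed over loci), and the multiplicatively
#' combined exclusion probability.
#'
#' @param x a [spatial_genotypes] table.
#' @param hwe,null_alleles,exclusion logical switches for the more
#'   expensive columns.
#' @param mc dememorization / batch settings passed to
#'   [hwe_exact_test()].
#' @param seed seed for the Hardy-Weinberg Markov chain.
#' @return A data.frame of class `diversity_summary` with one row per
#'   locus plus an `Overall` row.
#' @export
genetic_diversity <- function(x, hwe = TRUE, null_alleles = TRUE,
                              exclusion = TRUE,
                              mc = list(dememorization = 10000,
                                        batches = 20,
                                        iter_per_batch = 5000),
                              seed = NULL) {
  stopifnot(inherits(x, "spatial_genotypes"))
  loci <- dimnames(x$geno)[[3]]
  codes <- .codes(x$geno, x$loci)
  af <- allele_freqs(x)
  n_loci <- length(loci)
  A <- He <- f <- hwe_p <- null <- excl <- rep(NA_real_, n_loci)
  Bsum <- Csum <- 0
  for (l in seq_len(n_loci)) {
    p <- af$freqs[[l]]
    n2 <- af$n_genes[l]
    A[l] <- length(p)
    He[l] <- n2 / (n2 - 1) * (1 - sum(p^2))
    comp <- .wc_components(codes[[l]])
    if (!is.null(comp)) {
      f[l] <- 1 - sum(comp$c) / sum(comp$b + comp$c)
      Bsum <- Bsum + sum(comp$b)
      Csum <- Csum + sum(comp$c)
    }
    if (hwe)
      hwe_p[l] <- hwe_exact_test(codes[[l]],
                                 dememorization = mc$dememorization,
                                 batches = mc$batches,
                                 iter_per_batch = mc$iter_per_batch,
                                 seed = if (is.null(seed)) NULL else seed + l)$p
    if (null_alleles) null[l] <- null_allele_freq(codes[[l]])
    if (exclusion) excl[l] <- .exclusion_locus(p)
  }
  overall <- data.frame(
    locus = "Overall", A = sum(A), He = mean(He),
    f = 1 - Csum / (Bsum + Csum),
    hwe_p = NA_real_, null = NA_real_,
    excl = if (exclusion) combined_exclusion(excl) else NA_real_)
  out <- rbind(data.frame(locus = loci, A = A, He = He, f = f,
                          hwe_p = hwe_p, null = null, excl = excl),
               overall)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  cat("Genetic diversity summary (per locus and overall)\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], function(v) round(v, digits))
  print(y, row.names = FALSE)
  invisible(x)
}

# ---- Hardy-Weinberg exact test ------------------------------------------

## log conditional probability of a genotype table given allele counts,
## up to a constant: h*log(2) - sum(log(n_g!))
.hwe_logp <- function(counts_mat) {
  ut <- counts_mat[upper.tri(counts_mat, diag = TRUE)]
  h <- sum(counts_mat[upper.tri(counts_mat)])
  h * log(2) - sum(lgamma(ut + 1))
}

#' Markov-chain exact test of Hardy-Weinberg proportions
#'
#' Monte Carlo estimate of the exact Hardy-Weinberg probability test:
#' a switch chain swaps alleles between random individuals, which leaves
#' the uniform distribution over allele pairings (and hence the exact
#' conditional null over genotype tables) invariant. The p-value is the
#' fraction of visited tables with conditional probability not exceeding
#' that of the observed table. Default chain settings are 10000
#' dememorization steps, 20 batches and 5000 iterations per batch; the
#' standard error is computed over batch means.
#'
#' @param x a [spatial_genotypes] table, or an `n x 2` integer matrix of
#'   allele codes for one locus.
#' @param locus locus name when `x` is a table.
#' @param dememorization,batches,iter_per_batch chain settings.
#' @param seed optional seed.
#' @return List with `p`, `se` and `n_steps`. Monomorphic loci have a
#'   defined p-value of 1.
#' @export
hwe_exact_test <- function(x, locus = NULL, dememorization = 10000,
                           batches = 20, iter_per_batch = 5000,
                           seed = NULL) {
  g <- if (is.matrix(x)) x else {
    stopifnot(inherits(x, "spatial_genotypes"))
    if (is.null(locus)) stop("locus must be named")
    .codes(x$geno, x$loci)[[locus]]
  }
  g <- g[!is.na(g[, 1]), , drop = FALSE]
  k <- length(unique(c(g)))
  if (k < 2) return(list(p = 1, se = 0, n_steps = 0L))
  if (!is.null(seed)) set.seed(seed)
  g <- t(apply(g, 1, sort))
  kmax <- max(g)
  counts <- matrix(0L, kmax, kmax)
  for (i in seq_len(nrow(g))) {
    counts[g[i, 1], g[i, 2]] <- counts[g[i, 1], g[i, 2]] + 1L
  }
  obs_logp <- .hwe_logp(counts)
  cur_logp <- obs_logp
  n <- nrow(g)
  total <- dememorization + batches * iter_per_batch
  below <- numeric(batches)
  batch <- 0L
  in_batch <- 0L
  hits <- 0L
  ii <- sample.int(n, total, replace = TRUE)
  jj <- sample.int(n, total, replace = TRUE)
  si <- sample.int(2, total, replace = TRUE)
  sj <- sample.int(2, total, replace = TRUE)
  for (step in seq_len(total)) {
    i <- ii[step]; j <- jj[step]
    if (i != j) {
      gi <- g[i, ]; gj <- g[j, ]
      ai <- gi[si[step]]; aj <- gj[sj[step]]
      if (ai != aj) {
        ni <- sort(c(gi[3L - si[step]], aj))
        nj <- sort(c(gj[3L - sj[step]], ai))
        ## remove old, add new genotype counts; update logP incrementally
        d <- 0
        dec <- function(a, b) {
          c0 <- counts[a, b]
          counts[a, b] <<- c0 - 1L
          d <<- d + log(c0) - (if (a != b) log(2) else 0)
        }
        inc <- function(a, b) {
          c0 <- counts[a, b]
          counts[a, b] <<- c0 + 1L
          d <<- d - log(c0 + 1) + (if (a != b) log(2) else 0)
        }
        dec(gi[1], gi[2]); dec(gj[1], gj[2])
        inc(ni[1], ni[2]); inc(nj[1], nj[2])
        cur_logp <- cur_logp + d
        g[i, ] <- ni; g[j, ] <- nj
      }
    }
    if (step > dememorization) {
      if (cur_logp <= obs_logp + 1e-9) hits <- hits + 1L
      in_batch <- in_batch + 1L
      if (in_batch == iter_per_batch) {
        batch <- batch + 1L
        below[batch] <- hits / iter_per_batch
        hits <- 0L
        in_batch <- 0L
      }
    }
  }
  list(p = mean(below), se = sd(below) / sqrt(batches),
       n_steps = total)
}

# ---- null alleles --------------------------------------------------------

#' EM estimate of a single null-allele frequency
#'
#' Fits, by expectation-maximisation, a model in which a non-amplifying
#' allele of frequency r hides as apparent homozygotes (a null/visible
#' heterozygote scores as a homozygote for the visible allele) and
#' null/null genotypes are unobserved (the likelihood conditions on
#' observability). Returns approximately 0 when there is no homozygote
#' excess.
#'
#' @param x a [spatial_genotypes] table or an `n x 2` allele-code matrix.
#' @param locus locus name when `x` is a table.
#' @param tol,max_iter convergence controls.
#' @return The estimated null-allele frequency.
#' @export
null_allele_freq <- function(x, locus = NULL, tol = 1e-8, max_iter = 2000) {
  g <- if (is.matrix(x)) x else {
    stopifnot(inherits(x, "spatial_genotypes"))
    .codes(x$geno, x$loci)[[locus]]
  }
  g <- g[!is.na(g[, 1]), , drop = FALSE]
  k <- max(g)
  if (length(unique(c(g))) < 2) return(0)
  n <- nrow(g)
  hom <- tabulate(g[g[, 1] == g[, 2], 1], k)
  hetc <- tabulate(c(g[g[, 1] != g[, 2], ]), k)
  p <- (2 * hom + hetc) / (2 * n)
  r <- 0.05
  p <- p * (1 - r)
  for (it in seq_len(max_iter)) {
    n00 <- n * r^2 / (1 - r^2)
    denom <- p + 2 * r
    a0 <- ifelse(hom > 0, hom * 2 * r / denom, 0)
    true_aa <- hom - a0
    cnt <- 2 * true_aa + hetc + a0
    c0 <- sum(a0) + 2 * n00
    tot <- 2 * (n + n00)
    p_new <- cnt / tot
    r_new <- c0 / tot
    if (max(abs(c(p_new - p, r_new - r))) < tol) {
      r <- r_new
      break
    }
    p <- p_new
    r <- r_new
  }
  max(r, 0)
}

# ---- exclusion probabilities --------------------------------------------

## exact known-mother exclusion probability at one locus: probability
## that a random non-father is Mendelian-incompatible with a random
## mother-offspring pair, all genotypes in Hardy-Weinberg proportions
.exclusion_locus <- function(p) {
  k <- length(p)
  p <- as.numeric(p)
  E <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pm <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      if (pm == 0) next
      for (mat in unique(c(i, j))) {
        wm <- if (i == j) 1 else 0.5
        ## offspring = {mat, c}, paternal allele c from the frequencies
        for (cc in seq_len(k)) {
          o <- c(mat, cc)
          S <- integer(0)
          if (o[1] %in% c(i, j)) S <- c(S, o[2])
          if (o[2] %in% c(i, j)) S <- c(S, o[1])
          pS <- sum(p[unique(S)])
          E <- E + pm * wm * p[cc] * (1 - pS)^2
        }
      }
    }
  }
  E
}

#' Paternity exclusion probabilities (mother known)
#'
#' Per-locus probability that a randomly chosen non-father is genetically
#' incompatible with a random mother-offspring pair when the mother is
#' known, computed exactly from allele frequencies by enumeration over
#' mother, offspring and non-father genotypes in Hardy-Weinberg
#' proportions; combined across loci as `1 - prod(1 - E_l)`.
#'
#' @param freqs an `allele_freqs` object or a list of per-locus frequency
#'   vectors.
#' @return List with `per_locus` (named vector) and `combined`.
#' @export
exclusion_probability <- function(freqs) {
  fl <- if (inherits(freqs, "allele_freqs")) freqs$freqs else freqs
  per <- vapply(fl, .exclusion_locus, 0)
  list(per_locus = per, combined = combined_exclusion(per))
}

#' Combine per-locus exclusion probabilities
#'
#' @param per_locus vector of per-locus exclusion probabilities.
#' @return Combined exclusion probability `1 - prod(1 - E_l)`.
#' @export
combined_exclusion <- function(per_locus) {
  stopifnot(all(per_locus >= 0 & per_locus <= 1))
  1 - prod(1 - per_locus)
}
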