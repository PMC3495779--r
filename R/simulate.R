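# Synthetic-data generator: adults, genotypes and progeny arrays under a
# known spatial mating model, with a truth ledger for validating every
# downstream estimator.

#' Define a simulation scenario
#'
#' The defaults emulate the study system the package was designed around:
#' a dioecious wind-pollinated shrub population of 164 males and 29
#' sampled mothers on a 1000 x 700 m plot, seven microsatellite loci with
#' 3-18 alleles, adult inbreeding F = 0.152, a fat-tailed
#' power-exponential pollen kernel, high pollen immigration and strongly
#' skewed male fecundities.
#'
#' @param n_males,n_females numbers of adult males and females.
#' @param n_mothers number of sampled mothers (<= `n_females`).
#' @param plot_dim plot extent `c(x, y)` in metres.
#' @param spatial `"uniform"` or `"clustered"`.
#' @param n_clusters,cluster_sd clustered mode: number of cluster centres
#'   and the within-cluster standard deviation (m).
#' @param cluster_relatedness probability that an allele of a clustered
#'   individual is copied from its cluster's founder pool, producing
#'   kinship that decays with distance.
#' @param n_alleles integer vector, alleles per locus.
#' @param freqs optional list of per-locus allele frequency vectors; when
#'   `NULL` frequencies are drawn from a flat Dirichlet at simulation
#'   time.
#' @param F adult inbreeding coefficient used when drawing genotypes.
#' @param kernel kernel family: `"power_exponential"`, `"exponential"`,
#'   `"normal"`, `"geometric"` or `"uniform"` (flat, distance-free).
#' @param delta mean pollination distance of the kernel (m).
#' @param b kernel shape (power-exponential: `b < 1` is fat-tailed).
#' @param m pollen immigration rate in `[0, 1]`.
#' @param fecundity `"gamma"`, `"log_normal"` or `"equal"`.
#' @param fecundity_cv coefficient of variation of male fecundities.
#' @param habitat_effects optional named multiplicative fecundity effects
#'   for habitat classes `canopy`, `shrubland`, `hedge`.
#' @param seeds_per_mother seeds sampled per mother.
#' @param missing_rate per-locus probability that a seed genotype is
#'   missing.
#' @param outside_concentration Dirichlet concentration used to jitter
#'   the inside allele frequencies into the immigrant (outside) pollen
#'   pool; larger values keep the pools more similar.
#' @param mistyping_rate optional per-allele mistyping rate for
#'   robustness experiments; 0 by default (no error model).
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_males = 164, n_females = 29, n_mothers = n_females,
                         plot_dim = c(1000, 700),
                         spatial = c("uniform", "clustered"),
                         n_clusters = 12, cluster_sd = 30,
                         cluster_relatedness = 0.5,
                         n_alleles = c(14, 6, 18, 10, 15, 3, 3),
                         freqs = NULL, F = 0.152,
                         kernel = "power_exponential",
                         delta = 250, b = 0.5, m = 0.7,
                         fecundity = c("gamma", "log_normal", "equal"),
                         fecundity_cv = 1.5, habitat_effects = NULL,
                         seeds_per_mother = 24, missing_rate = 0.02,
                         outside_concentration = 50,
                         mistyping_rate = 0) {
  spatial <- match.arg(spatial)
  fecundity <- match.arg(fecundity)
  stopifnot(m >= 0, m <= 1, b > 0, delta > 0, fecundity_cv >= 0,
            n_mothers <= n_females, missing_rate >= 0, missing_rate < 1,
            all(n_alleles >= 1))
  if (!is.null(freqs)) {
    sums <- vapply(freqs, sum, 0)
    if (any(abs(sums - 1) > 1e-8))
      stop("allele frequencies must sum to 1 per locus")
  }
  structure(list(
    n_males = n_males, n_females = n_females, n_mothers = n_mothers,
    plot_dim = plot_dim, spatial = spatial, n_clusters = n_clusters,
    cluster_sd = cluster_sd, cluster_relatedness = cluster_relatedness,
    n_alleles = n_alleles, freqs = freqs, F = F,
    kernel = kernel, delta = delta, b = b, m = m,
    fecundity = fecundity, fecundity_cv = fecundity_cv,
    habitat_effects = habitat_effects,
    seeds_per_mother = seeds_per_mother, missing_rate = missing_rate,
    outside_concentration = outside_concentration,
    mistyping_rate = mistyping_rate), class = "sim_scenario")
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

## one diploid genotype column pair per individual, with inbreeding F:
## with prob F the two alleles are identical by descent
.draw_genotypes <- function(n, freqs, F) {
  k <- length(freqs)
  a1 <- sample.int(k, n, replace = TRUE, prob = freqs)
  ibd <- runif(n) < F
  a2 <- ifelse(ibd, a1, sample.int(k, n, replace = TRUE, prob = freqs))
  cbind(a1, a2)
}

#' Simulate a spatially mapped adult population
#'
#' Genotypes are drawn per locus with genotype frequencies
#' `p^2 + F p (1 - p)` for homozygotes and `2 p q (1 - F)` for
#' heterozygotes. In clustered mode individuals are placed around cluster
#' centres and share alleles with cluster founder genotypes, so that
#' kinship decays with spatial distance.
#'
#' @param scenario a [sim_scenario].
#' @param seed integer seed for reproducibility.
#' @return A [spatial_genotypes] table. The generative allele frequencies
#'   are attached as attribute `"gen_freqs"` (a named list of per-locus
#'   frequency vectors, names = allele labels).
#' @export
simulate_adults <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  sc <- scenario
  n <- sc$n_males + sc$n_females
  L <- length(sc$n_alleles)
  loci <- sprintf("L%02d", seq_len(L))
  freqs <- sc$freqs
  if (is.null(freqs))
    freqs <- lapply(sc$n_alleles, function(k) .rdirichlet1(rep(1, k)))
  freqs <- lapply(freqs, function(p) setNames(p, seq_along(p)))
  names(freqs) <- loci

  if (sc$spatial == "uniform") {
    xy <- cbind(runif(n, 0, sc$plot_dim[1]), runif(n, 0, sc$plot_dim[2]))
    cluster <- rep(NA_integer_, n)
  } else {
    centres <- cbind(runif(sc$n_clusters, 0, sc$plot_dim[1]),
                     runif(sc$n_clusters, 0, sc$plot_dim[2]))
    cluster <- sample.int(sc$n_clusters, n, replace = TRUE)
    xy <- centres[cluster, , drop = FALSE] +
      matrix(rnorm(2 * n, 0, sc$cluster_sd), ncol = 2)
    xy[, 1] <- pmin(pmax(xy[, 1], 0), sc$plot_dim[1])
    xy[, 2] <- pmin(pmax(xy[, 2], 0), sc$plot_dim[2])
  }

  geno <- array(NA_character_, c(n, 2L, L), dimnames = list(NULL, NULL, loci))
  for (l in seq_len(L)) {
    g <- .draw_genotypes(n, freqs[[l]], sc$F)
    if (sc$spatial == "clustered") {
      ## founder pool: two diploid founders per cluster (4 alleles)
      fp <- matrix(sample.int(length(freqs[[l]]), 4 * sc$n_clusters,
                              replace = TRUE, prob = freqs[[l]]),
                   nrow = sc$n_clusters)
      for (slot in 1:2) {
        take <- runif(n) < sc$cluster_relatedness
        pick <- fp[cbind(cluster, sample.int(4, n, replace = TRUE))]
        g[take, slot] <- pick[take]
      }
    }
    geno[, 1, l] <- names(freqs[[l]])[g[, 1]]
    geno[, 2, l] <- names(freqs[[l]])[g[, 2]]
  }

  sex <- c(rep("male", sc$n_males), rep("female", sc$n_females))
  habitat <- if (!is.null(sc$habitat_effects)) {
    sample(names(sc$habitat_effects), n, replace = TRUE)
  } else {
    sample(c("canopy", "shrubland", "hedge"), n, replace = TRUE)
  }
  ind <- data.frame(
    id = sprintf("%s%03d", ifelse(sex == "male", "M", "F"),
                 c(seq_len(sc$n_males), seq_len(sc$n_females))),
    sex = sex, x = xy[, 1], y = xy[, 2], habitat = habitat,
    stringsAsFactors = FALSE)
  out <- spatial_genotypes(ind, geno)
  attr(out, "gen_freqs") <- freqs
  out
}

## kernel density value at distance d (2-D density up to a constant);
## used as a mating weight over the finite male roster
.kernel_value <- function(d, family, delta, b) {
  switch(family,
    uniform = rep(1, length(d)),
    power_exponential = {
      a <- delta * gamma(2 / b) / gamma(3 / b)
      exp(-(d / a)^b)
    },
    exponential = exp(-2 * d / delta),
    normal = {
      a <- delta * 2 / sqrt(pi)
      exp(-(d / a)^2)
    },
    geometric = {
      if (b <= 3) stop("geometric kernel needs shape > 3 for a finite mean")
      a <- delta * (b - 3) / 2
      (1 + d / a)^(-b)
    },
    stop("unknown kernel family: ", family))
}

#' Simulate mating and a progeny array with known truth
#'
#' For each seed of each sampled mother the paternal gamete is immigrant
#' with probability `m` (drawn from an outside allele pool obtained by
#' Dirichlet-jittering the inside frequencies); otherwise a father is
#' drawn among the males with probability proportional to
#' `fecundity_j * k(d_mj)`. The seed genotype is one random maternal
#' allele plus one paternal allele per locus; there is no mutation and,
#' by default, no genotyping error.
#'
#' @param adults a [spatial_genotypes] table from [simulate_adults].
#' @param scenario the [sim_scenario] used.
#' @param seed integer seed.
#' @return A list with elements `progeny` (a [progeny_array]) and `truth`
#'   (class `truth_ledger`): per-seed true father id (`"immigrant"` for
#'   outside pollen), realized mating distances, per-male sired counts,
#'   the male fecundities and the outside allele frequencies used.
#' @export
simulate_mating <- function(adults, scenario, seed = 1L) {
  stopifnot(inherits(adults, "spatial_genotypes"),
            inherits(scenario, "sim_scenario"))
  set.seed(seed + 1L)
  sc <- scenario
  males <- adults$ind[adults$ind$sex == "male", ]
  females <- adults$ind[adults$ind$sex == "female", ]
  if (!nrow(males)) stop("no males in the adult table")
  mothers <- females[seq_len(min(sc$n_mothers, nrow(females))), ]

  freqs <- attr(adults, "gen_freqs")
  if (is.null(freqs)) {
    af <- allele_freqs(adults)
    freqs <- af$freqs
  }
  loci <- dimnames(adults$geno)[[3]]
  L <- length(loci)

  out_freqs <- lapply(freqs, function(p) {
    q <- .rdirichlet1(p * sc$outside_concentration)
    setNames(q, names(p))
  })

  fec <- switch(sc$fecundity,
    equal = rep(1, nrow(males)),
    gamma = if (sc$fecundity_cv == 0) rep(1, nrow(males)) else
      rgamma(nrow(males), shape = 1 / sc$fecundity_cv^2,
             scale = sc$fecundity_cv^2),
    log_normal = {
      s2 <- log(1 + sc$fecundity_cv^2)
      rlnorm(nrow(males), -s2 / 2, sqrt(s2))
    })
  if (!is.null(sc$habitat_effects)) {
    eff <- sc$habitat_effects[males$habitat]
    eff[is.na(eff)] <- 1
    fec <- fec * as.numeric(eff)
  }
  if (all(fec == 0)) stop("all male fecundities are zero")

  D <- .pairwise_dist(as.matrix(mothers[c("x", "y")]),
                      as.matrix(males[c("x", "y")]))
  K <- matrix(.kernel_value(D, sc$kernel, sc$delta, sc$b), nrow(mothers))
  W <- sweep(K, 2, fec, "*")

  midx <- match(mothers$id, adults$ind$id)
  geno_codes <- .codes(adults$geno, adults$loci)

  n_seeds_per <- rep(sc$seeds_per_mother, nrow(mothers))
  total <- sum(n_seeds_per)
  seed_geno <- array(NA_character_, c(total, 2L, L),
                     dimnames = list(NULL, NULL, loci))
  seed_tab <- data.frame(seed_id = sprintf("S%04d", seq_len(total)),
                         mother_id = rep(mothers$id, n_seeds_per),
                         stringsAsFactors = FALSE)
  father <- character(total)
  dist_real <- rep(NA_real_, total)

  row0 <- 0L
  for (im in seq_len(nrow(mothers))) {
    ns <- n_seeds_per[im]
    rows <- row0 + seq_len(ns)
    row0 <- row0 + ns
    immig <- runif(ns) < sc$m
    w <- W[im, ]
    fidx <- rep(NA_integer_, ns)
    if (any(!immig)) {
      if (all(w == 0)) stop("all mating weights zero for mother ", mothers$id[im])
      fidx[!immig] <- sample.int(length(w), sum(!immig), replace = TRUE,
                                 prob = w)
    }
    father[rows] <- ifelse(immig, "immigrant", males$id[fidx])
    dist_real[rows] <- ifelse(immig, NA_real_, D[im, fidx])
    for (l in seq_len(L)) {
      cat_l <- adults$loci[[loci[l]]]
      mg <- geno_codes[[l]][midx[im], ]
      mat <- cat_l[mg[sample.int(2, ns, replace = TRUE)]]
      pat <- character(ns)
      if (any(immig)) {
        p <- out_freqs[[loci[l]]]
        pat[immig] <- sample(names(p), sum(immig), replace = TRUE, prob = p)
      }
      if (any(!immig)) {
        fg <- geno_codes[[l]][
          match(males$id[fidx[!immig]], adults$ind$id), , drop = FALSE]
        pick <- fg[cbind(seq_len(nrow(fg)), sample.int(2, nrow(fg),
                                                       replace = TRUE))]
        pat[!immig] <- cat_l[pick]
      }
      if (sc$mistyping_rate > 0) {
        for (vec in c("mat", "pat")) {
          v <- get(vec)
          err <- runif(ns) < sc$mistyping_rate
          if (any(err))
            v[err] <- sample(cat_l, sum(err), replace = TRUE)
          assign(vec, v)
        }
      }
      g <- cbind(mat, pat)
      ## an untyped parent locus propagates as a fully missing seed locus
      na <- is.na(g[, 1]) | is.na(g[, 2])
      g[na, ] <- NA_character_
      ## store unordered (sorted) pair
      swap <- g[, 1] > g[, 2]
      swap[is.na(swap)] <- FALSE
      g[swap, ] <- g[swap, c(2, 1)]
      seed_geno[rows, , l] <- g
    }
  }

  if (sc$missing_rate > 0) {
    drop <- matrix(runif(total * L) < sc$missing_rate, total, L)
    for (l in seq_len(L)) {
      seed_geno[drop[, l], 1, l] <- NA_character_
      seed_geno[drop[, l], 2, l] <- NA_character_
    }
  }

  progeny <- progeny_array(seed_tab, seed_geno, adults)
  sired <- table(factor(father, levels = males$id))
  truth <- structure(list(
    fathers = data.frame(seed_id = seed_tab$seed_id,
                         mother_id = seed_tab$mother_id,
                         father_id = father, distance = dist_real,
                         stringsAsFactors = FALSE),
    sired_counts = setNames(as.integer(sired), males$id),
    fecundities = setNames(fec, males$id),
    outside_freqs = out_freqs,
    inside_freqs = freqs,
    scenario = sc), class = "truth_ledger")
  list(progeny = progeny, truth = truth)
}

#' @export
print.truth_ledger <- function(x, ...) {
  n <- nrow(x$fathers)
  ni <- sum(x$fathers$father_id == "immigrant")
  cat(sprintf(
    "Truth ledger: %d seeds, %d (%.1f%%) immigrant; kernel %s delta=%g b=%g, m=%g\n",
    n, ni, 100 * ni / n, x$scenario$kernel, x$scenario$delta,
    x$scenario$b, x$scenario$m))
  invisible(x)
}
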