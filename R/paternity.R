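# Likelihood-based paternity: LOD scores against a random-father model,
# simulation-calibrated assignment threshold, seed categorisation with
# spatial tie-breaking, immigration bounds, and the mating network.

#' Mendelian transition probability
#'
#' Probability of an offspring genotype given both parental genotypes
#' under Mendelian segregation with no genotyping error.
#'
#' @param offspring,mother,father length-2 vectors of allele labels.
#' @return P(offspring | mother, father).
#' @export
transition_probability <- function(offspring, mother, father) {
  stopifnot(length(offspring) == 2, length(mother) == 2, length(father) == 2)
  p <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      pair <- sort(c(mother[i], father[j]))
      if (identical(sort(as.character(offspring)), as.character(pair)))
        p <- p + 0.25
    }
  }
  p
}

## align a frequency list to a locus catalogue, applying a small floor to
## observed-but-absent alleles so that likelihood ratios stay finite
.align_freqs <- function(freqs, catalog, floor = 1e-4) {
  fl <- if (inherits(freqs, "allele_freqs")) freqs$freqs else freqs
  out <- vector("list", length(catalog))
  for (l in seq_along(catalog)) {
    nm <- names(catalog)[l]
    p <- fl[[nm]]
    if (is.null(p)) stop("no reference frequencies for locus ", nm)
    v <- setNames(rep(0, length(catalog[[l]])), catalog[[l]])
    v[names(p)] <- p
    if (any(v == 0) && floor > 0) v[v == 0] <- floor
    out[[l]] <- v / sum(v)
  }
  names(out) <- names(catalog)
  out
}

## paternal-compatibility weight vectors: for seed {a, b} with mother M,
## v[x] is P(seed | mother, father transmitting x); the likelihood of any
## father is then linear in his transmission probabilities
.seed_weight_rows <- function(seed_codes, mother_codes, k) {
  n <- nrow(seed_codes)
  V <- matrix(0, n, k)
  s1 <- seed_codes[, 1]; s2 <- seed_codes[, 2]
  m1 <- mother_codes[, 1]; m2 <- mother_codes[, 2]
  ok <- !is.na(s1) & !is.na(m1)
  pmv <- function(x) 0.5 * ((x == m1) + (x == m2))
  for (i in which(ok)) {
    a <- s1[i]; b <- s2[i]
    if (a == b) {
      V[i, a] <- 0.5 * ((a == m1[i]) + (a == m2[i]))
    } else {
      V[i, a] <- 0.5 * ((b == m1[i]) + (b == m2[i]))
      V[i, b] <- 0.5 * ((a == m1[i]) + (a == m2[i]))
    }
  }
  list(V = V, ok = ok)
}

## core LOD engine over integer-coded genotypes
## seed_codes/mother_codes: per-locus n x 2; male_codes: per-locus M x 2
.lod_engine <- function(seed_codes, mother_codes, male_codes, p_list) {
  L <- length(seed_codes)
  n <- nrow(seed_codes[[1]])
  M <- nrow(male_codes[[1]])
  LOD <- matrix(0, n, M)
  used <- integer(n)
  for (l in seq_len(L)) {
    k <- length(p_list[[l]])
    sw <- .seed_weight_rows(seed_codes[[l]], mother_codes[[l]], k)
    if (!any(sw$ok)) next
    f1 <- male_codes[[l]][, 1]; f2 <- male_codes[[l]][, 2]
    Mt <- matrix(0, M, k)
    okm <- !is.na(f1)
    for (a in seq_len(k))
      Mt[okm, a] <- 0.5 * ((f1[okm] == a) + (f2[okm] == a))
    numer <- sw$V %*% t(Mt)             # n x M
    denom <- as.numeric(sw$V %*% p_list[[l]])
    contrib <- log(numer) - log(denom)  # -Inf where incompatible
    contrib[!sw$ok, ] <- 0
    contrib[, !okm] <- 0                # untyped male: locus skipped
    denom_bad <- sw$ok & (denom <= 0)
    contrib[denom_bad, ] <- 0           # uninformative (defensive)
    LOD <- LOD + contrib
    used <- used + as.integer(sw$ok)
  }
  list(LOD = LOD, n_loci = used)
}

#' LOD scores of all candidate males for all seeds
#'
#' For each seed and candidate male, the LOD score is the summed
#' log-likelihood ratio over typed loci of the candidate fathering the
#' seed versus a random father drawn from the reference allele
#' frequencies (inbreeding coefficient `F`; the marginal transmission
#' probabilities of an inbred random father equal the allele frequencies,
#' so `F` enters through the threshold simulations rather than the
#' score itself). Loci with missing data in seed or mother are skipped
#' for that seed; loci with a missing candidate genotype are skipped for
#' that candidate. Mendelian-incompatible candidates score `-Inf`.
#'
#' @param progeny a [progeny_array].
#' @param adults a [spatial_genotypes] table with the mothers and the
#'   candidate males.
#' @param ref_freqs reference allele frequencies (an `allele_freqs`
#'   object, e.g. from [paternal_pool_freqs()]).
#' @param F inbreeding coefficient of the random-father genotype model.
#' @param freq_floor floor applied to observed alleles absent from the
#'   reference frequencies.
#' @return Object of class `lod_table`: list with `LOD` (seeds x males
#'   matrix), `n_loci` (typed loci used per seed), `males` and `seeds`.
#' @export
lod_scores <- function(progeny, adults, ref_freqs, F = 0, freq_floor = 1e-4) {
  stopifnot(inherits(progeny, "progeny_array"),
            inherits(adults, "spatial_genotypes"))
  loci <- dimnames(progeny$geno)[[3]]
  fl <- if (inherits(ref_freqs, "allele_freqs")) ref_freqs$freqs else ref_freqs
  catalog <- .union_catalog(adults$loci, progeny$loci,
                            lapply(fl, names))[loci]
  p_list <- .align_freqs(ref_freqs, catalog, freq_floor)
  sc <- .codes(progeny$geno, catalog)
  ac <- .codes(adults$geno, catalog)
  midx <- match(progeny$seeds$mother_id, adults$ind$id)
  male_rows <- which(adults$ind$sex == "male")
  mother_codes <- lapply(ac, function(m) m[midx, , drop = FALSE])
  male_codes <- lapply(ac, function(m) m[male_rows, , drop = FALSE])
  eng <- .lod_engine(sc, mother_codes, male_codes, p_list)
  dimnames(eng$LOD) <- list(progeny$seeds$seed_id,
                            adults$ind$id[male_rows])
  structure(list(LOD = eng$LOD, n_loci = eng$n_loci,
                 males = adults$ind$id[male_rows],
                 seeds = progeny$seeds, F = F),
            class = "lod_table")
}

#' LOD score for a single seed/mother/candidate trio
#'
#' @param seed,mother,candidate per-locus genotypes: `2 x n_loci`
#'   matrices (or named lists of length-2 vectors) of allele labels.
#' @param ref_freqs named list of per-locus allele frequency vectors.
#' @param F inbreeding coefficient (see [lod_scores()]).
#' @return The LOD score (`-Inf` if the candidate is Mendelian
#'   incompatible at any typed locus).
#' @export
lod_score <- function(seed, mother, candidate, ref_freqs, F = 0) {
  as_mat <- function(g) if (is.list(g)) do.call(cbind, g) else as.matrix(g)
  sg <- as_mat(seed); mg <- as_mat(mother); fg <- as_mat(candidate)
  loci <- names(ref_freqs)
  if (is.null(colnames(sg))) colnames(sg) <- loci
  total <- 0
  for (l in seq_along(loci)) {
    s <- sg[, l]; m <- mg[, l]; f <- fg[, l]
    if (anyNA(s) || anyNA(m) || anyNA(f)) next
    p <- ref_freqs[[l]]
    num <- transition_probability(s, m, f)
    ## denominator: random father transmits allele x with probability p_x
    den <- 0
    for (x in names(p)) {
      v <- 0
      for (i in 1:2) {
        pair <- sort(c(m[i], x))
        if (identical(sort(as.character(s)), as.character(pair)))
          v <- v + 0.5
      }
      den <- den + p[[x]] * v
    }
    if (den <= 0) next
    total <- total + log(num) - log(den)
  }
  total
}

#' Calibrate the LOD assignment threshold by simulation
#'
#' Simulates two sets of offspring from the sampled mothers: seeds whose
#' father is drawn among the candidate males, and seeds whose paternal
#' gamete is generated from the reference allele frequencies (random
#' fathers with inbreeding `F`). The threshold TF is the abscissa where
#' Gaussian kernel density estimates of the two most-likely-father LOD
#' distributions intersect, searched between the two distribution means.
#'
#' @inheritParams lod_scores
#' @param adults candidate males and sampled mothers.
#' @param n_sim number of synthetic seeds per distribution.
#' @param seed integer seed.
#' @param mothers optional character vector of mother ids (default: all
#'   females of `adults`).
#' @return List of class `lod_threshold` with `TF`, the two best-LOD
#'   samples, and the share of random-father seeds with no compatible
#'   male.
#' @export
calibrate_lod_threshold <- function(adults, ref_freqs, F = 0,
                                    n_sim = 50000, seed = 1L,
                                    mothers = NULL, freq_floor = 1e-4) {
  stopifnot(inherits(adults, "spatial_genotypes"), n_sim >= 1000)
  set.seed(seed)
  loci <- dimnames(adults$geno)[[3]]
  fl <- if (inherits(ref_freqs, "allele_freqs")) ref_freqs$freqs else ref_freqs
  catalog <- .union_catalog(adults$loci, lapply(fl, names))[loci]
  p_list <- .align_freqs(ref_freqs, catalog, freq_floor)
  ac <- .codes(adults$geno, catalog)
  male_rows <- which(adults$ind$sex == "male")
  if (is.null(mothers)) mothers <- adults$ind$id[adults$ind$sex == "female"]
  mrows <- match(mothers, adults$ind$id)
  male_codes <- lapply(ac, function(m) m[male_rows, , drop = FALSE])

  sim_best <- function(inside) {
    mi <- sample(mrows, n_sim, replace = TRUE)
    fi <- if (inside) sample(male_rows, n_sim, replace = TRUE) else NULL
    seed_codes <- mother_codes <- vector("list", length(loci))
    for (l in seq_along(loci)) {
      mc <- ac[[l]][mi, , drop = FALSE]
      mat <- mc[cbind(seq_len(n_sim), sample.int(2, n_sim, TRUE))]
      if (inside) {
        fc <- ac[[l]][fi, , drop = FALSE]
        pat <- fc[cbind(seq_len(n_sim), sample.int(2, n_sim, TRUE))]
      } else {
        p <- p_list[[l]]
        ## random father with inbreeding F, transmitting one allele
        k <- length(p)
        a1 <- sample.int(k, n_sim, replace = TRUE, prob = p)
        ibd <- runif(n_sim) < F
        a2 <- ifelse(ibd, a1, sample.int(k, n_sim, replace = TRUE, prob = p))
        pat <- ifelse(runif(n_sim) < 0.5, a1, a2)
      }
      sc <- cbind(mat, pat)
      sc[is.na(mat) | is.na(pat), ] <- NA_integer_
      seed_codes[[l]] <- sc
      mother_codes[[l]] <- mc
    }
    eng <- .lod_engine(seed_codes, mother_codes, male_codes, p_list)
    best <- apply(eng$LOD, 1, max)
    best[is.finite(best)]
  }

  best_in <- sim_best(TRUE)
  best_out <- sim_best(FALSE)
  no_comp <- 1 - length(best_out) / n_sim

  if (length(best_out) < 10) {
    ## markers so informative that random-father seeds are (almost)
    ## never compatible with any male: supports are fully separated
    warning("random-father seeds are almost never compatible with any ",
            "candidate; LOD distributions are completely separated")
    up_out <- if (length(best_out)) max(best_out) else 0
    TF <- (up_out + min(best_in)) / 2
    return(structure(list(TF = TF, best_inside = best_in,
                          best_random = best_out,
                          prop_no_compatible = no_comp, n_sim = n_sim,
                          F = F, seed = seed),
                     class = "lod_threshold"))
  }
  d_in <- density(best_in)
  d_out <- density(best_out)
  lo <- min(mean(best_out), mean(best_in))
  hi <- max(mean(best_out), mean(best_in))
  grid <- seq(lo, hi, length.out = 512)
  f_in <- approx(d_in$x, d_in$y, grid, rule = 2)$y
  f_out <- approx(d_out$x, d_out$y, grid, rule = 2)$y
  dd <- f_in - f_out
  cross <- which(diff(sign(dd)) != 0)
  if (!length(cross)) {
    warning("LOD score densities do not cross between their means; ",
            "using the midpoint of the distribution supports")
    TF <- (max(best_out) + min(best_in)) / 2
  } else {
    ## take the crossing where both densities are largest (the main one)
    sc_cross <- pmin(f_in[cross], f_out[cross])
    TF <- grid[cross[which.max(sc_cross)]]
    if (max(sc_cross) < 1e-6)
      warning("poor separation between LOD score distributions; ",
              "threshold lies in a near-zero density region")
  }
  structure(list(TF = TF, best_inside = best_in, best_random = best_out,
                 prop_no_compatible = no_comp, n_sim = n_sim, F = F,
                 seed = seed),
            class = "lod_threshold")
}

#' @export
print.lod_threshold <- function(x, ...) {
  cat(sprintf(
    "LOD assignment threshold TF = %.2f (n_sim = %d per distribution, F = %.3f)\n",
    x$TF, x$n_sim, x$F))
  cat(sprintf("inside-sired best-LOD mean %.2f; random-father best-LOD mean %.2f\n",
              mean(x$best_inside), mean(x$best_random)))
  invisible(x)
}

#' Assign paternity and categorise seeds
#'
#' Seeds are placed into three categories: `no_compatible_father` (no
#' Mendelian-compatible male in the site), `compatible_below_TF` (all
#' compatible males score below the threshold), and `assigned` (at least
#' one male above TF; paternity goes to the spatially closest such male).
#' Seeds typed at fewer than `min_loci` loci are excluded with a notice.
#'
#' @inheritParams lod_scores
#' @param TF LOD assignment threshold (from [calibrate_lod_threshold()]).
#' @param min_loci minimum typed loci per seed.
#' @return Object of class `paternity_result`: per-seed table with
#'   category, assigned father, best LOD, mating distance (m) and bearing
#'   (degrees, father to mother), plus category counts.
#' @export
assign_paternity <- function(progeny, adults, TF, ref_freqs, F = 0,
                             min_loci = progeny$min_loci,
                             freq_floor = 1e-4) {
  stopifnot(is.finite(TF))
  lt <- lod_scores(progeny, adults, ref_freqs, F, freq_floor)
  keep <- lt$n_loci >= min_loci
  if (any(!keep))
    message(sum(!keep), " seeds typed at < ", min_loci,
            " usable loci excluded from paternity analysis")
  seeds <- lt$seeds
  n <- nrow(seeds)
  category <- rep(NA_character_, n)
  father <- rep(NA_character_, n)
  lod_best <- rep(NA_real_, n)
  distance <- rep(NA_real_, n)
  bearing <- rep(NA_real_, n)
  male_xy <- as.matrix(adults$ind[match(lt$males, adults$ind$id),
                                  c("x", "y")])
  mom_xy <- as.matrix(adults$ind[match(seeds$mother_id, adults$ind$id),
                                 c("x", "y")])
  for (i in which(keep)) {
    lods <- lt$LOD[i, ]
    comp <- is.finite(lods)
    if (!any(comp)) {
      category[i] <- "no_compatible_father"
      next
    }
    lod_best[i] <- max(lods[comp])
    if (lod_best[i] <= TF) {
      category[i] <- "compatible_below_TF"
      next
    }
    category[i] <- "assigned"
    above <- which(comp & lods > TF)
    d <- sqrt((male_xy[above, 1] - mom_xy[i, 1])^2 +
              (male_xy[above, 2] - mom_xy[i, 2])^2)
    j <- above[which.min(d)]
    father[i] <- lt$males[j]
    distance[i] <- min(d)
    bearing[i] <- bearing_deg(male_xy[j, ], mom_xy[i, ])
  }
  tab <- data.frame(seeds[c("seed_id", "mother_id")],
                    n_loci = lt$n_loci, analysed = keep,
                    category = category, father_id = father,
                    lod_best = lod_best, distance = distance,
                    bearing = bearing, stringsAsFactors = FALSE)
  counts <- c(no_compatible_father = sum(category == "no_compatible_father",
                                         na.rm = TRUE),
              compatible_below_TF = sum(category == "compatible_below_TF",
                                        na.rm = TRUE),
              assigned = sum(category == "assigned", na.rm = TRUE))
  structure(list(seeds = tab, counts = counts, n_analysed = sum(keep),
                 TF = TF, F = F, males = lt$males),
            class = "paternity_result")
}

#' @export
print.paternity_result <- function(x, ...) {
  n <- x$n_analysed
  cat(sprintf("Paternity analysis of %d seeds (TF = %.2f, F = %.3f)\n",
              n, x$TF, x$F))
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                100 * x$counts[[nm]] / n))
  ib <- immigration_bounds(x)
  cat(sprintf("Pollen immigration between %.1f%% and %.1f%%\n",
              100 * ib[1], 100 * ib[2]))
  invisible(x)
}

#' @export
summary.paternity_result <- function(object, ...) {
  d <- object$seeds$distance[object$seeds$category == "assigned" &
                             !is.na(object$seeds$category)]
  list(counts = object$counts, immigration = immigration_bounds(object),
       distance_mean = mean(d), distance_sd = sd(d),
       distance_range = range(d))
}

#' Minimum and maximum pollen immigration rates
#'
#' The minimum rate counts only seeds with no compatible father in the
#' site; the maximum additionally counts seeds whose compatible fathers
#' all fell below the assignment threshold (these may or may not have a
#' true local father).
#'
#' @param result a [paternity_result].
#' @return Numeric vector `c(min, max)` of immigration-rate bounds.
#' @export
immigration_bounds <- function(result) {
  stopifnot(inherits(result, "paternity_result"))
  n <- result$n_analysed
  if (n == 0) stop("empty paternity result")
  ni <- result$counts[["no_compatible_father"]]
  nii <- result$counts[["compatible_below_TF"]]
  c(min = ni / n, max = (ni + nii) / n)
}

#' Mating network of assigned pollination events
#'
#' @param result a [paternity_result].
#' @param adults the [spatial_genotypes] table used in the assignment.
#' @return Object of class `mating_network`: `edges` (father, mother,
#'   n_seeds, distance, bearing), per-seed `distances` and `bearings`,
#'   `sired_counts` over all males (zeros included), and a distance
#'   summary.
#' @export
mating_network <- function(result, adults) {
  stopifnot(inherits(result, "paternity_result"))
  s <- result$seeds
  a <- s[!is.na(s$category) & s$category == "assigned", ]
  if (!nrow(a)) stop("no assigned seeds")
  key <- paste(a$father_id, a$mother_id, sep = "\r")
  agg <- do.call(rbind, lapply(split(a, key), function(g) {
    data.frame(father_id = g$father_id[1], mother_id = g$mother_id[1],
               n_seeds = nrow(g), distance = g$distance[1],
               bearing = g$bearing[1], stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  sired <- table(factor(a$father_id, levels = result$males))
  structure(list(
    edges = agg, distances = a$distance, bearings = a$bearing,
    sired_counts = setNames(as.integer(sired), result$males),
    summary = list(mean = mean(a$distance), sd = sd(a$distance),
                   range = range(a$distance),
                   prop_males_not_siring = mean(sired == 0))),
    class = "mating_network")
}

#' @export
print.mating_network <- function(x, ...) {
  cat(sprintf(
    "Mating network: %d events over %d father-mother edges\n",
    length(x$distances), nrow(x$edges)))
  cat(sprintf("mating distance mean %.0f m (SD %.0f, range %.0f-%.0f)\n",
              x$summary$mean, x$summary$sd, x$summary$range[1],
              x$summary$range[2]))
  cat(sprintf("%.0f%% of males sired no seed\n",
              100 * x$summary$prop_males_not_siring))
  invisible(x)
}
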