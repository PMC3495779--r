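# Mating-system estimation: multilocus and single-locus outcrossing
# rates under the mixed mating model (Newton-Raphson in t with joint
# pollen-pool frequency updates), family bootstrap, within-mother
# correlated paternity, effective number of fathers, and its relation
# to nearest-male distances.

## per-seed per-locus building blocks of the mixed mating likelihood:
## A = P(seed | mother, outcross to pollen pool q), S = P(seed | selfed)
.matsys_blocks <- function(progeny, adults) {
  loci <- dimnames(progeny$geno)[[3]]
  catalog <- .union_catalog(adults$loci, progeny$loci)[loci]
  sc <- .codes(progeny$geno, catalog)
  ac <- .codes(adults$geno, catalog)
  midx <- match(progeny$seeds$mother_id, adults$ind$id)
  if (anyNA(midx)) stop("seeds with unknown mothers")
  n <- nrow(progeny$seeds)
  V <- Tm <- vector("list", length(loci))
  usable <- matrix(FALSE, n, length(loci))
  for (l in seq_along(loci)) {
    k <- length(catalog[[l]])
    mom <- ac[[l]][midx, , drop = FALSE]
    sw <- .seed_weight_rows(sc[[l]], mom, k)
    ## mother's own transmission vector (selfing component)
    Tmat <- matrix(0, n, k)
    ok <- sw$ok
    for (a in seq_len(k))
      Tmat[ok, a] <- 0.5 * ((mom[ok, 1] == a) + (mom[ok, 2] == a))
    ## a seed sharing no allele with its mother cannot be scored under
    ## the mixed model: treat the locus as missing for that seed
    bad <- ok & rowSums(sw$V) == 0
    usable[, l] <- ok & !bad
    V[[l]] <- sw$V
    Tm[[l]] <- Tmat
  }
  list(V = V, Tm = Tm, usable = usable, catalog = catalog,
       mothers = progeny$seeds$mother_id)
}

## EM with a Newton-Raphson t-step for one locus set (multilocus when
## `loci` is all of them, single-locus otherwise)
.fit_mixed_mating <- function(blocks, q0, loci, tol = 1e-10,
                              max_iter = 500, t0 = 0.9) {
  n <- nrow(blocks$usable)
  q <- q0[loci]
  t <- t0
  ll_old <- -Inf
  pinned <- FALSE
  for (iter in seq_len(max_iter)) {
    A <- rep(1, n); S <- rep(1, n)
    Wx <- vector("list", length(loci))
    for (ii in seq_along(loci)) {
      l <- loci[ii]
      u <- blocks$usable[, l]
      Al <- as.numeric(blocks$V[[l]] %*% q[[ii]])
      Sl <- rowSums(blocks$V[[l]] * blocks$Tm[[l]])
      A[u] <- A[u] * Al[u]
      S[u] <- S[u] * Sl[u]
      Wx[[ii]] <- sweep(blocks$V[[l]], 2, q[[ii]], "*")
    }
    keep <- A > 0 | S > 0
    den <- t * A + (1 - t) * S
    ll <- sum(log(den[keep & den > 0]))
    ## Newton-Raphson for t given the current pollen-pool frequencies
    for (nr in 1:50) {
      den <- t * A + (1 - t) * S
      u2 <- (A - S)[keep & den > 0] / den[keep & den > 0]
      g <- sum(u2)
      H <- -sum(u2^2)
      if (abs(g) < 1e-10 || H == 0) break
      t_new <- t - g / H
      if (t_new >= 1) { t <- 1 - 1e-9; pinned <- g > 0; break }
      if (t_new <= 0) { t <- 1e-9; pinned <- g < 0; break }
      if (abs(t_new - t) < 1e-12) { t <- t_new; break }
      t <- t_new
    }
    ## E-step responsibilities and pollen-frequency update
    den <- t * A + (1 - t) * S
    r <- ifelse(den > 0, t * A / den, 0)
    for (ii in seq_along(loci)) {
      l <- loci[ii]
      u <- blocks$usable[, l]
      Al <- as.numeric(blocks$V[[l]] %*% q[[ii]])
      w <- Wx[[ii]] / ifelse(Al > 0, Al, 1)
      w[!u | Al <= 0, ] <- 0
      cnt <- colSums(w * r)
      if (sum(cnt) > 0) q[[ii]] <- cnt / sum(cnt)
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(t = t, q = q, loglik = ll, iterations = iter, pinned = pinned)
}

#' Multilocus and single-locus outcrossing rates
#'
#' Fits the mixed mating model: each seed is an outcross (probability
#' `t`, paternal gamete from a pollen pool whose allele frequencies are
#' estimated jointly) or a self (probability `1 - t`, both gametes from
#' the mother). `tm` maximises the multilocus likelihood by
#' Newton-Raphson in `t` alternated with pollen-frequency updates; `ts`
#' is the arithmetic mean of per-locus estimates. Biparental inbreeding
#' is quantified as `tm - ts`, with significance from a paired t-test
#' over bootstrap replicates resampling whole maternal families. For a
#' dioecious species literal selfing is impossible and `1 - tm` and
#' `tm - ts` measure apparent selfing caused by mating among relatives.
#'
#' @param progeny a [progeny_array].
#' @param adults the [spatial_genotypes] table with the mothers.
#' @param n_boot bootstrap replicates over families (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `mating_system`: `tm`, `ts`, `tm_ts`,
#'   per-locus `ts_by_locus`, the family-bootstrap draws, their SDs and
#'   the paired t-test of `tm - ts`.
#' @export
estimate_outcrossing <- function(progeny, adults, n_boot = 1000,
                                 seed = 1L) {
  stopifnot(inherits(progeny, "progeny_array"))
  fam <- unique(progeny$seeds$mother_id)
  if (length(fam) < 2) stop("need at least 2 families")
  set.seed(seed)
  blocks <- .matsys_blocks(progeny, adults)
  pg <- paternal_gametes(progeny, adults)
  q0 <- lapply(pg$W, function(w) {
    cs <- colSums(w) + 1e-6
    cs / sum(cs)
  })
  loci <- seq_along(blocks$V)

  point <- .point_outcrossing(blocks, q0, loci)
  boot_tm <- boot_ts <- numeric(n_boot)
  if (n_boot > 0) {
    for (r in seq_len(n_boot)) {
      pick <- sample(fam, length(fam), replace = TRUE)
      rows <- unlist(lapply(pick, function(mm)
        which(blocks$mothers == mm)))
      bb <- list(V = lapply(blocks$V, function(v) v[rows, , drop = FALSE]),
                 Tm = lapply(blocks$Tm, function(v) v[rows, , drop = FALSE]),
                 usable = blocks$usable[rows, , drop = FALSE],
                 mothers = blocks$mothers[rows])
      est <- .point_outcrossing(bb, q0, loci, max_iter = 200)
      boot_tm[r] <- est$tm
      boot_ts[r] <- est$ts
    }
  }
  tt <- if (n_boot > 1 && sd(boot_tm - boot_ts) > 0)
    t.test(boot_tm, boot_ts, paired = TRUE) else NULL
  structure(list(tm = point$tm, ts = point$ts,
                 tm_ts = point$tm - point$ts,
                 ts_by_locus = point$ts_by_locus,
                 boot_tm = boot_tm, boot_ts = boot_ts,
                 se_tm = if (n_boot > 1) sd(boot_tm) else NA_real_,
                 se_ts = if (n_boot > 1) sd(boot_ts) else NA_real_,
                 t_test = tt, n_boot = n_boot,
                 n_seeds = nrow(blocks$usable), n_families = length(fam)),
            class = "mating_system")
}

.point_outcrossing <- function(blocks, q0, loci, max_iter = 500) {
  fit_m <- .fit_mixed_mating(blocks, q0, loci, max_iter = max_iter)
  ts_l <- vapply(loci, function(l)
    .fit_mixed_mating(blocks, q0, l, max_iter = max_iter)$t, 0)
  list(tm = fit_m$t, ts = mean(ts_l), ts_by_locus = ts_l)
}

#' @export
print.mating_system <- function(x, ...) {
  cat(sprintf(
    "Mixed mating model: tm = %.3f, ts = %.3f, biparental inbreeding tm - ts = %.3f\n",
    x$tm, x$ts, x$tm_ts))
  if (!is.null(x$t_test))
    cat(sprintf(
      "family bootstrap (%d reps): SE(tm) = %.3f, SE(ts) = %.3f; paired t = %.2f, P = %.3g\n",
      x$n_boot, x$se_tm, x$se_ts, x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}

#' Within-mother correlated paternity
#'
#' `rp` is twice the average pairwise Loiselle kinship (haploid mode)
#' between the inferred paternal gametes of seed pairs of the same
#' mother, i.e. the probability that two seeds of a mother share a
#' father; also returned per mother. Mothers with fewer than 2 usable
#' seeds are skipped with a notice.
#'
#' @param progeny a [progeny_array].
#' @param adults the [spatial_genotypes] table with the mothers.
#' @param freqs reference allele frequencies for the kinship estimator
#'   (default: the paternal pool itself).
#' @return Object of class `correlated_paternity`: `rp`, `per_mother`
#'   (named vector) and pair counts.
#' @export
correlated_paternity <- function(progeny, adults, freqs = NULL) {
  pg <- paternal_gametes(progeny, adults)
  kin <- loiselle_kinship(pg, freqs = freqs)
  mothers <- unique(progeny$seeds$mother_id)
  Fm <- kin$F
  fin <- is.finite(Fm)
  F0 <- ifelse(fin, Fm, 0)
  rp_m <- n_m <- setNames(rep(NA_real_, length(mothers)), mothers)
  for (mm in mothers) {
    rows <- which(progeny$seeds$mother_id == mm)
    if (length(rows) < 2) next
    sub_f <- F0[rows, rows]
    sub_n <- fin[rows, rows]
    s <- sum(sub_f[upper.tri(sub_f)][sub_n[upper.tri(sub_n)]])
    np <- sum(sub_n[upper.tri(sub_n)])
    if (np > 0) {
      rp_m[mm] <- 2 * s / np
      n_m[mm] <- np
    }
  }
  skipped <- sum(is.na(rp_m))
  if (skipped)
    message(skipped, " mothers with < 2 usable seeds skipped")
  w <- n_m[!is.na(rp_m)]
  rp <- sum(rp_m[!is.na(rp_m)] * w) / sum(w)
  structure(list(rp = rp, per_mother = rp_m, n_pairs = n_m,
                 Nep = effective_fathers(rp)),
            class = "correlated_paternity")
}

#' @export
print.correlated_paternity <- function(x, ...) {
  cat(sprintf(
    "Correlated paternity rp = %.3f (effective number of fathers Nep = %.1f)\n",
    x$rp, x$Nep))
  cat(sprintf("per-mother rp range %.3f-%.3f over %d mothers\n",
              min(x$per_mother, na.rm = TRUE),
              max(x$per_mother, na.rm = TRUE),
              sum(!is.na(x$per_mother))))
  invisible(x)
}

#' Effective number of pollen donors
#'
#' @param rp within-mother correlated paternity (> 0).
#' @return `Nep = 1 / rp`; `NA` (not estimable) when `rp <= 0`.
#' @export
effective_fathers <- function(rp) {
  if (!is.finite(rp) || rp <= 0) {
    message("rp <= 0: effective number of fathers not estimable")
    return(NA_real_)
  }
  1 / rp
}

#' Correlate per-mother rp with nearest-male distances
#'
#' Pearson correlation of per-mother correlated paternity with the log
#' mean distance to each mother's k nearest males, for each k in
#' `k_list`.
#'
#' @param per_mother named vector of per-mother rp values (names are
#'   mother ids), e.g. from [correlated_paternity()].
#' @param adults the [spatial_genotypes] table.
#' @param k_list numbers of nearest males to average over.
#' @return data.frame with columns `k`, `r`, `p`, `n`.
#' @export
rp_vs_nearest_males <- function(per_mother, adults, k_list = c(1, 3, 5)) {
  per_mother <- per_mother[!is.na(per_mother)]
  moms <- names(per_mother)
  males <- adults$ind[adults$ind$sex == "male", ]
  stopifnot(nrow(males) >= max(k_list))
  D <- .pairwise_dist(
    as.matrix(adults$ind[match(moms, adults$ind$id), c("x", "y")]),
    as.matrix(males[c("x", "y")]))
  out <- lapply(k_list, function(k) {
    dk <- apply(D, 1, function(d) mean(sort(d)[seq_len(k)]))
    if (sd(per_mother) == 0 || sd(dk) == 0)
      return(data.frame(k = k, r = NA_real_, p = NA_real_,
                        n = length(moms)))
    ct <- cor.test(per_mother, log(dk))
    data.frame(k = k, r = unname(ct$estimate), p = ct$p.value,
               n = length(moms))
  })
  do.call(rbind, out)
}
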