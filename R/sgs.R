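# Fine-scale spatial genetic structure: Loiselle kinship (diploid
# individuals or haploid gametes), kinship-on-log-distance regression
# with location permutations, distance-class correlograms with jackknife
# and permutation envelopes, and the Sp statistic.

## per-locus individual allele-frequency rows: diploid 0/0.5/1 from a
## code matrix, haploid fractional rows straight from gamete weights
.allele_rows_diploid <- function(codes, k) {
  n <- nrow(codes)
  X <- matrix(0, n, k)
  ok <- !is.na(codes[, 1])
  for (a in seq_len(k))
    X[ok, a] <- 0.5 * ((codes[ok, 1] == a) + (codes[ok, 2] == a))
  list(X = X, typed = ok, copies = 2L)
}

#' Loiselle pairwise kinship coefficients
#'
#' Computes the Loiselle et al. kinship estimator between all pairs:
#' per locus, the numerator sums over alleles the products of centred
#' individual allele frequencies plus the finite-sample correction term
#' `p(1-p)/(n_genes - 1)`, and the denominator is `sum p(1-p)`; the
#' multilocus coefficient is the ratio of numerator and denominator sums
#' over loci (monomorphic loci contribute zero to both and are
#' effectively skipped). Diploid mode uses half-counts (0, 0.5, 1);
#' haploid mode uses gamete allele indicators, with ambiguous inferred
#' gametes entering through their fractional Mendelian weights (the
#' kinship of two fractional gametes is the weight-averaged kinship).
#'
#' @param x a [spatial_genotypes] table (diploid mode) or a
#'   [paternal_gametes] object (haploid mode).
#' @param freqs reference allele frequencies; defaults to frequencies
#'   computed from the analysed sample itself.
#' @return Object of class `kinship_matrix`: `F` (pairwise kinship),
#'   plus per-locus numerator matrices and denominators retained for
#'   jackknifing, `typed` indicators, `ids` and `mode`.
#' @export
loiselle_kinship <- function(x, freqs = NULL) {
  if (inherits(x, "spatial_genotypes")) {
    mode <- "diploid"
    catalog <- x$loci
    if (is.null(freqs)) freqs <- allele_freqs(x)
    codes <- .codes(x$geno, catalog)
    rows <- lapply(seq_along(codes), function(l)
      .allele_rows_diploid(codes[[l]], length(catalog[[l]])))
    ids <- x$ind$id
  } else if (inherits(x, "paternal_gametes")) {
    mode <- "haploid"
    catalog <- x$catalog
    if (is.null(freqs)) freqs <- paternal_pool_freqs(x)
    rows <- lapply(seq_along(x$W), function(l) {
      W <- x$W[[l]]
      list(X = W, typed = rowSums(W) > 0, copies = 1L)
    })
    ids <- x$seeds$seed_id
  } else stop("x must be a spatial_genotypes or paternal_gametes object")

  fl <- if (inherits(freqs, "allele_freqs")) freqs$freqs else freqs
  loci <- names(catalog)
  n <- length(ids)
  num_l <- vector("list", length(loci))
  den_l <- numeric(length(loci))
  typed <- matrix(FALSE, n, length(loci))
  num_sum <- matrix(0, n, n)
  den_sum <- matrix(0, n, n)
  for (l in seq_along(loci)) {
    ## reference frequencies may name alleles unseen in this sample:
    ## align over the union, with zero indicator columns for those
    ref <- fl[[loci[l]]]
    extra <- setdiff(names(ref), catalog[[l]])
    lev <- c(catalog[[l]], extra)
    p <- setNames(rep(0, length(lev)), lev)
    p[names(ref)] <- ref
    D <- sum(p * (1 - p))
    r <- rows[[l]]
    if (length(extra))
      r$X <- cbind(r$X, matrix(0, n, length(extra)))
    typed[, l] <- r$typed
    if (D <= 0) { num_l[[l]] <- matrix(0, n, n); den_l[l] <- 0; next }
    ng <- sum(r$typed) * r$copies
    C <- sweep(r$X, 2, p)
    C[!r$typed, ] <- 0
    t_num <- as.numeric(r$typed)
    M <- tcrossprod(C) + outer(t_num, t_num) * (D / (ng - 1))
    num_l[[l]] <- M
    den_l[l] <- D
    num_sum <- num_sum + M
    den_sum <- den_sum + D * outer(t_num, t_num)
  }
  Fm <- num_sum / den_sum
  Fm[den_sum == 0] <- NA_real_
  diag(Fm) <- NA_real_
  dimnames(Fm) <- list(ids, ids)
  structure(list(F = Fm, num_l = num_l, den_l = den_l, typed = typed,
                 ids = ids, mode = mode, loci = loci),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Loiselle kinship matrix (%s mode): %d x %d, %d loci\n",
              x$mode, length(x$ids), length(x$ids), length(x$loci)))
  cat(sprintf("mean pairwise Fij = %.4f\n", mean(x$F, na.rm = TRUE)))
  invisible(x)
}

## pair indices of the upper triangle with finite F and positive distance
.pair_frame <- function(kin, coords, max_dist = NULL) {
  n <- length(kin$ids)
  D <- .pairwise_dist(as.matrix(coords))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  f <- kin$F[ut]
  keep <- is.finite(f) & d > 0
  zero <- sum(d == 0 & is.finite(f))
  if (!is.null(max_dist)) keep <- keep & d <= max_dist
  list(i = ut[keep, 1], j = ut[keep, 2], d = d[keep], f = f[keep],
       n_zero_excluded = zero)
}

#' Regression of pairwise kinship on log distance
#'
#' The slope `b-log` of pairwise Loiselle kinship on the natural
#' logarithm of spatial distance (the standard measure of fine-scale
#' structure in two dimensions), with significance from randomly
#' permuting the spatial locations of individuals. The test is one-sided
#' for structure (negative slope) by default. Coincident pairs (zero
#' distance) are excluded and counted.
#'
#' @param kin a `kinship_matrix` from [loiselle_kinship()].
#' @param coords two-column matrix or data.frame of x/y coordinates, in
#'   the same order as the kinship matrix.
#' @param n_perm number of location permutations (0 for slope only).
#' @param seed integer seed.
#' @param max_dist optional maximum pair distance (m).
#' @param alternative `"negative"` (one-sided, default) or
#'   `"two_sided"`.
#' @return List of class `sgs_regression` with `b_log`, `p`, `n_pairs`
#'   and the permutation slopes.
#' @export
sgs_regression <- function(kin, coords, n_perm = 1000, seed = NULL,
                           max_dist = NULL,
                           alternative = c("negative", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(kin, "kinship_matrix"))
  if (!is.null(seed)) set.seed(seed)
  pf <- .pair_frame(kin, coords, max_dist)
  if (pf$n_zero_excluded)
    message(pf$n_zero_excluded, " coincident pairs excluded")
  lnd <- log(pf$d)
  if (var(lnd) == 0 || var(pf$f) == 0)
    stop("zero variance in distances or kinship; slope undefined")
  slope <- function(fv) cov(fv, lnd) / var(lnd)
  b_obs <- slope(pf$f)
  perm_slopes <- NULL
  p <- NA_real_
  if (n_perm > 0) {
    n <- length(kin$ids)
    perm_slopes <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      pr <- sample.int(n)
      fv <- kin$F[cbind(pr[pf$i], pr[pf$j])]
      perm_slopes[r] <- slope(fv)
    }
    p <- if (alternative == "negative")
      (1 + sum(perm_slopes <= b_obs)) / (n_perm + 1)
    else
      (1 + sum(abs(perm_slopes) >= abs(b_obs))) / (n_perm + 1)
  }
  structure(list(b_log = b_obs, p = p, n_perm = n_perm,
                 n_pairs = length(pf$f), alternative = alternative,
                 perm_slopes = perm_slopes),
            class = "sgs_regression")
}

#' @export
print.sgs_regression <- function(x, ...) {
  cat(sprintf("Kinship on ln(distance): b-log = %.5f", x$b_log))
  if (!is.na(x$p))
    cat(sprintf(" (permutation P = %.4g, %d permutations, %s)",
                x$p, x$n_perm, x$alternative))
  cat(sprintf("; %d pairs\n", x$n_pairs))
  invisible(x)
}

#' Spatial genetic structure correlogram
#'
#' Average pairwise kinship per distance class, with approximate 95%
#' confidence intervals as twice the standard error from jackknifing
#' over loci, a permutation envelope from randomly permuting individual
#' locations, the kinship-on-log-distance slope restricted to the same
#' maximal distance, and the Sp statistic `b_log / (F1 - 1)` where F1 is
#' the mean kinship in the first class.
#'
#' @inheritParams sgs_regression
#' @param class_edges strictly increasing upper edges of the distance
#'   classes; default 10 equal-width classes on (0, 460] m.
#' @return Object of class `sgs_correlogram` with the per-class table
#'   (`classes`), `b_log`, `p_slope`, `F1` and `Sp`.
#' @export
sgs_correlogram <- function(kin, coords, class_edges = seq(46, 460, by = 46),
                            n_perm = 1000, seed = NULL) {
  stopifnot(inherits(kin, "kinship_matrix"),
            all(diff(class_edges) > 0))
  if (!is.null(seed)) set.seed(seed)
  max_dist <- max(class_edges)
  pf <- .pair_frame(kin, coords, max_dist)
  cls <- findInterval(pf$d, c(0, class_edges), left.open = TRUE,
                      rightmost.closed = FALSE)
  n_cls <- length(class_edges)
  mean_f <- n_pairs <- rep(NA_real_, n_cls)
  for (c0 in seq_len(n_cls)) {
    sel <- cls == c0
    n_pairs[c0] <- sum(sel)
    if (n_pairs[c0] > 0) mean_f[c0] <- mean(pf$f[sel])
  }

  ## jackknife over loci: recompute class means dropping one locus
  L <- length(kin$loci)
  poly <- which(kin$den_l > 0)
  jack <- matrix(NA_real_, length(poly), n_cls)
  if (length(poly) > 1) {
    num_sum <- Reduce(`+`, kin$num_l[poly])
    tmat <- kin$typed
    den_sum <- matrix(0, nrow(num_sum), ncol(num_sum))
    for (l in poly) {
      t_num <- as.numeric(tmat[, l])
      den_sum <- den_sum + kin$den_l[l] * outer(t_num, t_num)
    }
    for (ii in seq_along(poly)) {
      l <- poly[ii]
      t_num <- as.numeric(tmat[, l])
      num_d <- num_sum - kin$num_l[[l]]
      den_d <- den_sum - kin$den_l[l] * outer(t_num, t_num)
      Fd <- num_d / den_d
      fv <- Fd[cbind(pf$i, pf$j)]
      for (c0 in seq_len(n_cls)) {
        sel <- cls == c0 & is.finite(fv)
        if (any(sel)) jack[ii, c0] <- mean(fv[sel])
      }
    }
  }
  jack_se <- apply(jack, 2, function(v) {
    v <- v[is.finite(v)]
    m <- length(v)
    if (m < 2) return(NA_real_)
    sqrt((m - 1) / m * sum((v - mean(v))^2))
  })

  ## permutation envelope per class
  env_lo <- env_hi <- rep(NA_real_, n_cls)
  if (n_perm > 0) {
    n <- length(kin$ids)
    pm <- matrix(NA_real_, n_perm, n_cls)
    for (r in seq_len(n_perm)) {
      pr <- sample.int(n)
      fv <- kin$F[cbind(pr[pf$i], pr[pf$j])]
      for (c0 in seq_len(n_cls)) {
        sel <- cls == c0
        if (any(sel)) pm[r, c0] <- mean(fv[sel], na.rm = TRUE)
      }
    }
    env_lo <- apply(pm, 2, quantile, 0.025, na.rm = TRUE)
    env_hi <- apply(pm, 2, quantile, 0.975, na.rm = TRUE)
  }

  reg <- sgs_regression(kin, coords, n_perm = n_perm, max_dist = max_dist)
  F1 <- mean_f[1]
  classes <- data.frame(
    upper = class_edges, n_pairs = n_pairs, mean_fij = mean_f,
    jack_se = jack_se, ci_lo = mean_f - 2 * jack_se,
    ci_hi = mean_f + 2 * jack_se, env_lo = env_lo, env_hi = env_hi,
    outside_envelope = !is.na(mean_f) & !is.na(env_lo) &
      (mean_f < env_lo | mean_f > env_hi))
  structure(list(classes = classes, b_log = reg$b_log, p_slope = reg$p,
                 F1 = F1, Sp = sp_statistic(reg$b_log, F1),
                 n_perm = n_perm, max_dist = max_dist),
            class = "sgs_correlogram")
}

#' @export
print.sgs_correlogram <- function(x, digits = 4, ...) {
  cat(sprintf(
    "SGS correlogram: %d classes to %.0f m; b-log = %.5f (P = %.4g), F(1) = %.4f, Sp = %.4f\n",
    nrow(x$classes), x$max_dist, x$b_log, x$p_slope, x$F1, x$Sp))
  y <- x$classes
  y[] <- lapply(y, function(v) if (is.numeric(v)) round(v, digits) else v)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sgs_correlogram <- function(x, ...) {
  cl <- x$classes
  mid <- cl$upper - diff(c(0, cl$upper)) / 2
  ylim <- range(c(cl$ci_lo, cl$ci_hi, cl$env_lo, cl$env_hi, 0),
                na.rm = TRUE)
  plot(mid, cl$mean_fij, type = "b", pch = ifelse(cl$outside_envelope, 1, 16),
       xlab = "distance (m)", ylab = "mean kinship Fij", ylim = ylim, ...)
  arrows(mid, cl$ci_lo, mid, cl$ci_hi, angle = 90, code = 3, length = 0.03)
  lines(mid, cl$env_lo, lty = 3)
  lines(mid, cl$env_hi, lty = 3)
  abline(h = 0, col = "grey")
  invisible(x)
}

#' Sp statistic of spatial genetic structure
#'
#' @param b_log slope of pairwise kinship on log distance.
#' @param F1 mean kinship among pairs in the first distance class
#'   (must be < 1).
#' @return `Sp = b_log / (F1 - 1)`.
#' @export
sp_statistic <- function(b_log, F1) {
  if (!is.finite(F1) || F1 >= 1) return(NA_real_)
  b_log / (F1 - 1)
}
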