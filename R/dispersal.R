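# Indirect pollen dispersal kernel estimation from the decay of
# correlated paternity among mother pairs, observed-versus-potential
# mating distance comparison, and directional (anisotropy) statistics.

# ---- kernel families -----------------------------------------------------

## 2-D dispersal kernel shape k(r) up to a normalisation constant
.kernel_shape <- function(r, family, a, b) {
  switch(family,
    power_exponential = exp(-(r / a)^b),
    exponential = exp(-r / a),
    normal = exp(-(r / a)^2),
    geometric = (1 + r / a)^(-b),
    stop("unknown kernel family: ", family))
}

#' Mean pollination distance of a dispersal kernel
#'
#' Closed-form mean distance `delta` of the two-dimensional kernel:
#' power-exponential `a G(3/b) / G(2/b)`, exponential `2a`, normal
#' (Gaussian) `a sqrt(pi) / 2`, geometric `2a / (b - 3)`.
#'
#' @param family kernel family, or a `dispersal_kernel` object.
#' @param a scale parameter (> 0).
#' @param b shape parameter (power-exponential: > 0; geometric: > 3 for
#'   a finite mean).
#' @return Mean pollination distance in the units of `a`.
#' @export
kernel_mean_distance <- function(family, a = NULL, b = NULL) {
  if (inherits(family, "dispersal_kernel")) {
    a <- family$a; b <- family$b; family <- family$family
  }
  stopifnot(a > 0)
  switch(family,
    power_exponential = {
      stopifnot(b > 0)
      a * gamma(3 / b) / gamma(2 / b)
    },
    exponential = 2 * a,
    normal = a * sqrt(pi) / 2,
    geometric = {
      if (is.null(b) || b <= 3)
        stop("geometric kernel mean distance diverges for shape <= 3")
      2 * a / (b - 3)
    },
    stop("unknown kernel family: ", family))
}

#' Dispersal kernel probability density
#'
#' Normalised two-dimensional probability density of pollination at
#' distance `r` (per square metre), i.e. `k(r)` such that the integral
#' of `k` over the plane is 1.
#'
#' @param r distances (m).
#' @param kernel a `dispersal_kernel` object, or a family name with `a`,
#'   `b` supplied.
#' @inheritParams kernel_mean_distance
#' @export
kernel_density <- function(r, kernel, a = NULL, b = NULL) {
  if (inherits(kernel, "dispersal_kernel")) {
    a <- kernel$a; b <- kernel$b; family <- kernel$family
  } else family <- kernel
  const <- switch(family,
    power_exponential = b / (2 * pi * a^2 * gamma(2 / b)),
    exponential = 1 / (2 * pi * a^2),
    normal = 1 / (pi * a^2),
    geometric = {
      stopifnot(b > 2)
      (b - 1) * (b - 2) / (2 * pi * a^2)
    },
    stop("unknown kernel family: ", family))
  const * .kernel_shape(r, family, a, b)
}

# ---- correlated paternity between mothers -------------------------------

#' Correlated paternity between mother pairs
#'
#' For every pair of sampled mothers, the correlated paternity is twice
#' the mean pairwise Loiselle kinship (haploid mode) between the
#' inferred paternal gametes of their seeds, paired with the
#' inter-mother distance. The within-mother value (twice the mean
#' kinship among gametes of the same mother, i.e. the correlated
#' paternity rp at distance zero) is retained for normalisation when a
#' kernel is fitted.
#'
#' @param progeny a [progeny_array].
#' @param adults the [spatial_genotypes] table with the mothers.
#' @param freqs reference allele frequencies for the kinship estimator
#'   (default: the paternal pool itself).
#' @return Object of class `copat_curve`: `pairs` (mother pair table
#'   with `distance`, `psi`, `n_pairs`), `psi0` (within-mother
#'   correlated paternity) and per-mother seed counts.
#' @export
copaternity_curve <- function(progeny, adults, freqs = NULL) {
  pg <- paternal_gametes(progeny, adults)
  kin <- loiselle_kinship(pg, freqs = freqs)
  mothers <- unique(progeny$seeds$mother_id)
  mi <- factor(progeny$seeds$mother_id, levels = mothers)
  A <- t(sapply(mothers, function(m) as.numeric(mi == m)))
  Fm <- kin$F
  fin <- is.finite(Fm)
  F0 <- ifelse(fin, Fm, 0)
  sums <- A %*% F0 %*% t(A)
  cnts <- A %*% fin %*% t(A)
  mean_between <- sums / cnts

  ## within-mother: same-block pairs excluding the diagonal (which is NA)
  psi0_by <- 2 * diag(sums) / diag(cnts)
  w <- as.numeric(diag(cnts))
  psi0 <- 2 * sum(diag(sums)) / sum(diag(cnts))

  xy <- as.matrix(adults$ind[match(mothers, adults$ind$id), c("x", "y")])
  D <- .pairwise_dist(xy)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- data.frame(
    mother_a = mothers[ut[, 1]], mother_b = mothers[ut[, 2]],
    distance = D[ut], psi = 2 * mean_between[ut],
    n_pairs = cnts[ut], stringsAsFactors = FALSE)
  pairs <- pairs[pairs$n_pairs > 0, ]
  structure(list(pairs = pairs, psi0 = psi0, psi0_by_mother = psi0_by,
                 mothers = mothers),
            class = "copat_curve")
}

#' @export
print.copat_curve <- function(x, ...) {
  cat(sprintf(
    "Correlated paternity curve: %d mother pairs, distances %.0f-%.0f m\n",
    nrow(x$pairs), min(x$pairs$distance), max(x$pairs$distance)))
  cat(sprintf("within-mother correlated paternity (psi at 0) = %.3f\n",
              x$psi0))
  invisible(x)
}

#' Decay of correlated paternity with log distance
#'
#' Pearson correlation of between-mother correlated paternity with the
#' natural log of inter-mother distance, the recommended precheck before
#' fitting a kernel to the decay curve.
#'
#' @param curve a `copat_curve` from [copaternity_curve()].
#' @return List with `r`, `p` (two-sided, t approximation) and `n`.
#' @export
copaternity_decay_test <- function(curve) {
  stopifnot(inherits(curve, "copat_curve"))
  if (nrow(curve$pairs) < 3) stop("need at least 3 mother pairs")
  if (var(curve$pairs$psi) == 0 || var(log(curve$pairs$distance)) == 0)
    stop("zero variance in correlated paternity or distances")
  ct <- cor.test(curve$pairs$psi, log(curve$pairs$distance))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(curve$pairs))
}

# ---- kernel fitting from the decay curve --------------------------------

## overlap integral O(z) of two pollen clouds with centres z apart,
## on a polar grid (log-spaced radii, uniform angles); the kernel
## normalisation constant cancels in the ratio O(z)/O(0)
.overlap_curve <- function(zs, family, a, b, delta, n_r, n_theta) {
  rmax <- 5 * delta
  u <- seq(log(delta * 1e-4), log(rmax), length.out = n_r)
  du <- u[2] - u[1]
  r <- exp(u)
  wr <- rep(du, n_r); wr[c(1, n_r)] <- du / 2
  base <- .kernel_shape(r, family, a, b) * r^2 * wr
  th <- seq(0, pi, length.out = n_theta)
  dth <- th[2] - th[1]
  wth <- rep(dth, n_theta); wth[c(1, n_theta)] <- dth / 2
  cth <- cos(th)
  O0 <- 2 * pi * sum(base * .kernel_shape(r, family, a, b))
  Oz <- vapply(zs, function(z) {
    if (z == 0) return(O0)
    D2 <- outer(r^2 + z^2, rep(1, n_theta)) - outer(2 * r * z, cth)
    D2[D2 < 0] <- 0
    kv <- .kernel_shape(sqrt(D2), family, a, b)
    2 * as.numeric(base %*% kv %*% wth)
  }, 0)
  list(O0 = O0, Oz = Oz)
}

#' Fit a pollen dispersal kernel to correlated-paternity decay
#'
#' Least-squares fit of a dispersal kernel to the normalised decay of
#' between-mother correlated paternity with distance. The baseline
#' (mean correlated paternity of mother pairs beyond the unrelatedness
#' threshold) is subtracted and the curve rescaled by the within-mother
#' value, so the observations estimate the model-predicted overlap of
#' two pollen clouds `O(z)/O(0)`, computed by numerical integration of
#' `k(.) k(. + z)` on a polar grid under a uniform effective father
#' density. Minimisation is over log-scale parameters by multi-start
#' Nelder-Mead to avoid the flat ridge of fat-tailed kernels.
#'
#' @param curve a `copat_curve`.
#' @param family kernel family (see [kernel_density()]).
#' @param threshold unrelatedness threshold distance (m) beyond which
#'   pollen clouds are treated as uncorrelated; default 300.
#' @param control list: `n_r`, `n_theta` polar grid nodes (default 256
#'   radial x 128 angular), `n_z` interpolation nodes for the overlap
#'   curve, `n_starts` Nelder-Mead starts, `maxit` iterations per start.
#' @return Object of class `dispersal_kernel` with the fitted scale `a`,
#'   shape `b`, derived mean distance `delta`, residual sum of squares
#'   `rss` and the normalised curve with fitted values.
#' @export
fit_dispersal_kernel <- function(curve,
                                 family = c("power_exponential",
                                            "exponential", "normal",
                                            "geometric"),
                                 threshold = 300, control = list()) {
  family <- match.arg(family)
  stopifnot(inherits(curve, "copat_curve"))
  ctrl <- modifyList(list(n_r = 256, n_theta = 128, n_z = 40,
                          n_starts = 9, maxit = 200), control)
  d <- curve$pairs$distance
  psi <- curve$pairs$psi
  far <- d > threshold
  if (!any(far) || !any(!far))
    stop("need mother pairs both below and beyond the threshold distance")
  baseline <- mean(psi[far])
  scale0 <- curve$psi0 - baseline
  if (scale0 <= 0)
    stop("within-mother correlated paternity does not exceed the baseline; ",
         "no decay signal to fit")
  y <- (psi - baseline) / scale0
  zg <- seq(0, max(d), length.out = ctrl$n_z)

  two_par <- family %in% c("power_exponential", "geometric")
  ## predicted normalised curve, with the same baseline subtraction the
  ## observations received: the model's mean overlap beyond the
  ## threshold plays the role of the empirical baseline
  pred_fun <- function(a, b) {
    ov <- .overlap_curve(zg[-1], family, a, b,
                         kernel_mean_distance(family, a, b),
                         ctrl$n_r, ctrl$n_theta)
    eta <- c(1, ov$Oz / ov$O0)
    eta_d <- approx(zg, eta, d, rule = 2)$y
    eta_far <- mean(eta_d[far])
    (eta_d - eta_far) / (1 - eta_far)
  }
  obj <- function(par) {
    a <- exp(par[1])
    b <- if (two_par) {
      if (family == "geometric") 3 + exp(par[2]) else exp(par[2])
    } else if (family == "normal") 2 else 1
    delta <- tryCatch(kernel_mean_distance(family, a, b),
                      error = function(e) NA_real_)
    if (!is.finite(delta) || delta <= 0 || delta > 50 * max(d))
      return(1e6)
    sum((y - pred_fun(a, b))^2)
  }

  med <- stats::median(d)
  if (two_par) {
    la0 <- log(med / 2) + c(-2, 0, 2)
    lb0 <- if (family == "geometric") log(c(0.3, 1.3, 4)) else
      log(c(0.25, 1, 3))
    starts <- as.matrix(expand.grid(la0, lb0))
    starts <- starts[seq_len(min(nrow(starts), ctrl$n_starts)), ,
                     drop = FALSE]
    fits <- lapply(seq_len(nrow(starts)), function(s)
      optim(starts[s, ], obj, method = "Nelder-Mead",
            control = list(maxit = ctrl$maxit, reltol = 1e-8)))
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    a <- exp(best$par[1])
    b <- if (family == "geometric") 3 + exp(best$par[2]) else
      exp(best$par[2])
    rss <- best$value
    conv <- best$convergence
  } else {
    op <- optimize(function(la) obj(la), interval = log(med) + c(-8, 4))
    a <- exp(op$minimum)
    b <- if (family == "normal") 2 else 1
    rss <- op$objective
    conv <- 0L
  }
  if (rss >= 1e6)
    stop("kernel fit did not converge (objective stuck at penalty value)")
  delta <- kernel_mean_distance(family, a, b)
  fitted <- pred_fun(a, b)
  if (two_par && (b <= 0.011 || b >= 9.9))
    warning("kernel shape parameter pinned near its bound")
  structure(list(family = family, a = a, b = b, delta = delta, rss = rss,
                 threshold = threshold, baseline = baseline,
                 psi0 = curve$psi0, convergence = conv,
                 curve = data.frame(distance = d, psi = psi,
                                    normalized = y, fitted = fitted),
                 control = ctrl),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf(
    "Dispersal kernel (%s): a = %.4g, b = %.3g, mean distance delta = %.1f m\n",
    x$family, x$a, x$b, x$delta))
  cat(sprintf("least-squares RSS = %.4g over %d mother pairs (threshold %g m)\n",
              x$rss, nrow(x$curve), x$threshold))
  invisible(x)
}

#' @export
coef.dispersal_kernel <- function(object, ...) {
  c(a = object$a, b = object$b, delta = object$delta)
}

#' @export
plot.dispersal_kernel <- function(x, ...) {
  o <- order(x$curve$distance)
  plot(x$curve$distance, x$curve$normalized, pch = 16, cex = 0.6,
       xlab = "inter-mother distance (m)",
       ylab = "normalised correlated paternity", ...)
  lines(x$curve$distance[o], x$curve$fitted[o], col = 2, lwd = 2)
  abline(h = 0, col = "grey")
  invisible(x)
}

# ---- observed vs potential mating distances -----------------------------

#' Compare observed and potential mating distance distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the observed mating distances
#' (from the paternity analysis) against the potential distribution:
#' the distances of all possible male x mother pairs.
#'
#' @param network a `mating_network` (or a numeric vector of observed
#'   mating distances).
#' @param adults the [spatial_genotypes] table (males and mothers).
#' @param n_perm if > 0, a permutation p-value is computed by drawing
#'   samples of the observed size from the potential set.
#' @param seed seed for the permutation option.
#' @return List with the KS statistic `d`, asymptotic `p`, optional
#'   `p_perm`, and the number of potential pairs.
#' @export
mating_distance_test <- function(network, adults, n_perm = 0, seed = NULL) {
  obs <- if (inherits(network, "mating_network")) network$distances
         else as.numeric(network)
  if (!length(obs)) stop("no observed mating events")
  males <- adults$ind[adults$ind$sex == "male", c("x", "y")]
  moms <- adults$ind[adults$ind$sex == "female", c("x", "y")]
  pot <- as.numeric(.pairwise_dist(as.matrix(males), as.matrix(moms)))
  kt <- suppressWarnings(ks.test(obs, pot))
  out <- list(d = unname(kt$statistic), p = kt$p.value,
              n_obs = length(obs), n_potential = length(pot))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    dperm <- replicate(n_perm, {
      suppressWarnings(ks.test(sample(pot, length(obs)), pot)$statistic)
    })
    out$p_perm <- (1 + sum(dperm >= out$d)) / (n_perm + 1)
  }
  out
}

# ---- circular statistics -------------------------------------------------

#' Watson's two-sample U-squared test for circular data
#'
#' Nonparametric comparison of two samples of angles (degrees). Ties
#' across samples are handled by processing tied values as one group.
#' The p-value uses the standard asymptotic series
#' `P(U2 > u) = 2 sum_k (-1)^(k-1) exp(-2 k^2 pi^2 u)`; an optional
#' permutation p-value is available for small samples.
#'
#' @param a,b numeric vectors of angles in degrees (>= 8 each).
#' @param n_perm if > 0, adds a permutation p-value.
#' @param seed seed for permutations.
#' @return List with `u2`, `p` and optionally `p_perm`.
#' @export
watson_u2_test <- function(a, b, n_perm = 0, seed = NULL) {
  a <- as.numeric(a) %% 360
  b <- as.numeric(b) %% 360
  if (length(a) < 8 || length(b) < 8)
    stop("need at least 8 bearings per sample")
  if (length(unique(c(a, b))) < 2)
    stop("all angles identical; test undefined")
  u2 <- .watson_u2_stat(a, b)
  out <- list(u2 = u2, p = .watson_u2_p(u2),
              n = c(length(a), length(b)))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    pool <- c(a, b)
    na <- length(a)
    stats_p <- replicate(n_perm, {
      idx <- sample.int(length(pool), na)
      .watson_u2_stat(pool[idx], pool[-idx])
    })
    out$p_perm <- (1 + sum(stats_p >= u2)) / (n_perm + 1)
  }
  out
}

.watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  vals <- c(a, b)
  grp <- c(rep(1L, n), rep(2L, m))
  o <- order(vals)
  vals <- vals[o]; grp <- grp[o]
  ## process tied values as one group so identical samples give u2 = 0
  uv <- unique(vals)
  d <- numeric(length(uv))
  w <- numeric(length(uv))
  ca <- 0L; cb <- 0L
  for (k in seq_along(uv)) {
    sel <- vals == uv[k]
    ca <- ca + sum(grp[sel] == 1L)
    cb <- cb + sum(grp[sel] == 2L)
    d[k] <- ca / n - cb / m
    w[k] <- sum(sel)
  }
  (n * m / N^2) * (sum(w * d^2) - sum(w * d)^2 / N)
}

.watson_u2_p <- function(u2, k_max = 100) {
  if (u2 <= 1e-10) return(1)
  k <- seq_len(k_max)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  min(max(p, 0), 1)
}

#' Sector counts for a wind-rose histogram
#'
#' @param bearings angles in degrees clockwise from north.
#' @param n_sectors number of equal sectors (default 16).
#' @return Object of class `rose`: counts per sector with mid-angles.
#' @export
rose_counts <- function(bearings, n_sectors = 16) {
  bearings <- as.numeric(bearings) %% 360
  width <- 360 / n_sectors
  ## sectors centred on 0, width/2, ...: shift by half a sector
  idx <- floor(((bearings + width / 2) %% 360) / width) + 1L
  counts <- tabulate(idx, n_sectors)
  structure(list(counts = counts, mid = (seq_len(n_sectors) - 1L) * width,
                 n = length(bearings)),
            class = "rose")
}

#' @export
print.rose <- function(x, ...) {
  cat(sprintf("Wind rose: %d observations in %d sectors\n",
              x$n, length(x$counts)))
  print(setNames(x$counts, paste0(x$mid, "°")))
  invisible(x)
}

#' @export
plot.rose <- function(x, ...) {
  fr <- x$counts / max(1, sum(x$counts))
  th <- (90 - x$mid) * pi / 180
  lim <- max(fr) * 1.1
  plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
       xlab = "", ylab = "", axes = FALSE, ...)
  for (k in seq_along(fr))
    segments(0, 0, fr[k] * cos(th[k]), fr[k] * sin(th[k]), lwd = 4)
  points(0, 0, pch = 16)
  invisible(x)
}
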