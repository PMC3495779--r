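# Bayesian spatially explicit mixed-effect mating model: joint posterior
# of the pollen dispersal kernel (delta, b), the immigration rate m, and
# per-male relative fecundities under a gamma or log-normal random-effect
# law (optionally with a habitat covariate on expected fecundity), fitted
# by Metropolis-within-Gibbs MCMC. Selfing is structurally zero (dioecy).

#' Priors for the mating model
#'
#' Uniform bounds for the observed-to-effective male density ratio, the
#' mean pollination distance delta (m), the kernel shape b and the
#' immigration rate m. The density ratio bound constrains the fecundity
#' dispersion: for independent fecundities the expected ratio is
#' `1 + CV^2`, so the dispersion parameter is given a uniform prior on
#' that scale. Selfing is fixed at zero.
#'
#' @param ratio,delta,b,m length-2 numeric vectors `c(min, max)`.
#' @return A list of class `memm_prior`.
#' @export
memm_prior <- function(ratio = c(1, 150), delta = c(50, 1500),
                       b = c(0.1, 10), m = c(0.4, 0.95)) {
  for (v in list(ratio, delta, b, m))
    stopifnot(length(v) == 2, v[1] < v[2])
  structure(list(ratio = ratio, delta = delta, b = b, m = m, s = 0),
            class = "memm_prior")
}

## seed x male likelihood-ratio matrix against the outside-pollen model:
## R_ij = P(seed_i | mother_i, male_j) / P(seed_i | mother_i, outside),
## products over typed loci; a male untyped at a locus contributes his
## population's marginal transmission probabilities
.memm_R_matrix <- function(progeny, adults, outside_freqs, floor = 1e-4,
                           min_loci = progeny$min_loci) {
  loci <- dimnames(progeny$geno)[[3]]
  fl <- if (inherits(outside_freqs, "allele_freqs")) outside_freqs$freqs
        else outside_freqs
  catalog <- .union_catalog(adults$loci, progeny$loci,
                            lapply(fl, names))[loci]
  p_out <- .align_freqs(outside_freqs, catalog, floor)
  p_in <- .align_freqs(allele_freqs(adults, subset = "male"),
                       catalog, floor)
  sc <- .codes(progeny$geno, catalog)
  ac <- .codes(adults$geno, catalog)
  keep <- progeny$seeds$n_loci >= min_loci
  midx_all <- match(progeny$seeds$mother_id, adults$ind$id)
  male_rows <- which(adults$ind$sex == "male")
  n <- sum(keep)
  M <- length(male_rows)
  logPin <- matrix(0, n, M)
  log_gout <- numeric(n)
  n_skipped <- 0L
  for (l in seq_along(loci)) {
    k <- length(catalog[[l]])
    swl <- .seed_weight_rows(sc[[l]][keep, , drop = FALSE],
                             ac[[l]][midx_all[keep], , drop = FALSE], k)
    ## a seed sharing no allele with its mother at a locus cannot be
    ## scored: skip the locus for that seed (same rule as the
    ## paternal-gamete module)
    vz <- swl$ok & rowSums(swl$V) == 0
    swl$ok <- swl$ok & !vz
    n_skipped <- n_skipped + sum(vz)
    if (!any(swl$ok)) next
    f1 <- ac[[l]][male_rows, 1]; f2 <- ac[[l]][male_rows, 2]
    Mt <- matrix(0, M, k)
    okm <- !is.na(f1)
    for (a in seq_len(k))
      Mt[okm, a] <- 0.5 * ((f1[okm] == a) + (f2[okm] == a))
    if (any(!okm))
      Mt[!okm, ] <- matrix(p_in[[l]], sum(!okm), k, byrow = TRUE)
    numer <- swl$V %*% t(Mt)
    dout <- as.numeric(swl$V %*% p_out[[l]])
    contrib <- log(numer)
    contrib[!swl$ok, ] <- 0
    logPin <- logPin + contrib
    log_gout <- log_gout + ifelse(swl$ok, log(dout), 0)
  }
  if (n_skipped)
    warning(n_skipped, " seed/mother-incompatible loci skipped")
  mothers <- unique(progeny$seeds$mother_id[keep])
  ## per-seed normalisation by the largest component keeps both mixture
  ## terms representable even when one of them underflows or is zero
  cmax <- pmax(log_gout, apply(logPin, 1, max))
  R <- exp(logPin - cmax)
  R[R < 1e-290] <- 0   # flush subnormal likelihood ratios
  gn <- exp(log_gout - cmax)
  gn[gn < 1e-290] <- 0
  list(R = R, gn = gn, log_scale = cmax,
       mom = match(progeny$seeds$mother_id[keep], mothers) - 1L,
       mothers = mothers, males = adults$ind$id[male_rows],
       seed_ids = progeny$seeds$seed_id[keep])
}

#' Conditional log-likelihood of the mating model
#'
#' For each seed of mother m the likelihood mixes immigrant pollen
#' (probability `m`, paternal gamete from the outside allele
#' frequencies) with local fathers j taken with probability
#' proportional to `f_j k(d_mj; delta, b)`. Ambiguous paternal gametes
#' are handled by summing genotype transition probabilities over
#' compatible paternal alleles with Mendelian weights.
#'
#' @param progeny a [progeny_array].
#' @param adults a [spatial_genotypes] table (mothers and males).
#' @param params list with `delta`, `b`, `m` and optionally
#'   `fecundities` (per-male relative fecundities, default equal).
#' @param outside_freqs allele frequencies of the immigrant pollen pool.
#' @param floor frequency floor for alleles absent from
#'   `outside_freqs`; set to 0 for strict evaluation (a seed impossible
#'   under both mixture components is then an error).
#' @return Total conditional log-likelihood over seeds.
#' @export
memm_loglik <- function(progeny, adults, params, outside_freqs,
                        floor = 0) {
  stopifnot(all(c("delta", "b", "m") %in% names(params)))
  dat <- .memm_R_matrix(progeny, adults, outside_freqs, floor = floor)
  f <- params$fecundities
  if (is.null(f)) f <- rep(1, length(dat$males))
  stopifnot(length(f) == length(dat$males), all(f > 0))
  moms_xy <- as.matrix(adults$ind[match(dat$mothers, adults$ind$id),
                                  c("x", "y")])
  males_xy <- as.matrix(adults$ind[match(dat$males, adults$ind$id),
                                   c("x", "y")])
  D <- .pairwise_dist(moms_xy, males_xy)
  K <- memm_kernel(D, params$delta, params$b)
  su <- memm_sums(dat$R, dat$mom, K, f)
  Sn <- su$T / su$W[dat$mom + 1L]
  Li <- params$m * dat$gn + (1 - params$m) * Sn
  zero <- which(!is.finite(Li) | Li <= 0 |
                  !is.finite(dat$log_scale))
  if (length(zero))
    stop("zero-likelihood seed(s) under both mixture components: ",
         paste(head(dat$seed_ids[zero]), collapse = ", "))
  sum(log(Li) + dat$log_scale)
}

#' Fit the Bayesian mixed-effect mating model
#'
#' Metropolis-within-Gibbs sampler: random-walk updates of log delta,
#' log b, the immigration rate m, the fecundity dispersion and the
#' habitat covariate effects, plus a Metropolis sweep over the per-male
#' fecundities under a gamma or log-normal random-effect law whose
#' expectation is tied to the covariate. Proposal step sizes adapt
#' towards a 20-40% acceptance rate during burn-in only, keeping the
#' post-burn-in chain Markovian.
#'
#' @param progeny a [progeny_array].
#' @param adults a [spatial_genotypes] table with mothers and males.
#' @param outside_freqs immigrant pollen-pool allele frequencies (an
#'   `allele_freqs` object or list), e.g. the paternal pool of seeds
#'   that could not be assigned locally.
#' @param prior a [memm_prior].
#' @param fecundity `"gamma"` or `"log_normal"` random-effect law.
#' @param covariate optional name of a column of `adults$ind` (e.g.
#'   `"habitat"`) entering as a multiplicative effect on expected male
#'   fecundity, first level as reference.
#' @param n_iter,burn_in total post-burn-in iterations and burn-in
#'   length (defaults mirror a full analysis; reduce for
#'   experimentation).
#' @param thin record every `thin`-th draw.
#' @param seed integer seed.
#' @param prior_only if `TRUE` the likelihood is switched off
#'   (prior-recovery runs).
#' @param verbose print progress.
#' @return Object of class `memm_fit`: `chains` (data.frame of recorded
#'   draws of delta, b, m, dispersion, density ratio, covariate effects
#'   and conditional log-likelihood), `f_draws` (matrix of mean-1
#'   normalised fecundity draws), posterior `summary`, `mean_loglik`
#'   (mean conditional log-likelihood over post-burn-in draws) and
#'   acceptance rates.
#' @export
memm <- function(progeny, adults, outside_freqs, prior = memm_prior(),
                 fecundity = c("gamma", "log_normal"), covariate = NULL,
                 n_iter = 100000, burn_in = 20000, thin = 20, seed = 1L,
                 prior_only = FALSE, verbose = FALSE) {
  fecundity <- match.arg(fecundity)
  stopifnot(inherits(prior, "memm_prior"), n_iter > 0, burn_in >= 0)
  set.seed(seed)
  dat <- .memm_R_matrix(progeny, adults, outside_freqs)
  nj <- length(dat$males)
  moms_xy <- as.matrix(adults$ind[match(dat$mothers, adults$ind$id),
                                  c("x", "y")])
  males_xy <- as.matrix(adults$ind[match(dat$males, adults$ind$id),
                                   c("x", "y")])
  D <- .pairwise_dist(moms_xy, males_xy)
  if (any(!is.finite(dat$log_scale)))
    stop("zero-likelihood seed(s) under both mixture components: ",
         paste(head(dat$seed_ids[!is.finite(dat$log_scale)]),
               collapse = ", "))
  const_ll <- sum(dat$log_scale)

  ## covariate design (multiplicative, first level = reference)
  X <- NULL
  lev <- NULL
  if (!is.null(covariate)) {
    vals <- adults$ind[match(dat$males, adults$ind$id), covariate]
    lev <- unique(vals)
    if (length(lev) > 1) {
      X <- sapply(lev[-1], function(lv) as.numeric(vals == lv))
      X <- matrix(X, nrow = nj)
    } else lev <- NULL
  }
  nbeta <- if (is.null(X)) 0L else ncol(X)

  ## state
  delta <- exp(mean(log(prior$delta)))
  b <- exp(mean(log(prior$b)))
  m <- mean(prior$m)
  lam <- 1                         # CV^2 of fecundities; ratio = 1 + lam
  beta <- rep(0, nbeta)
  f <- rep(1, nj)
  mu <- rep(1, nj)
  ptype <- if (fecundity == "gamma") 0L else 1L
  ppar <- function(lam) if (ptype == 0L) 1 / lam else log(1 + lam)

  K <- memm_kernel(D, delta, b)
  su <- memm_sums(dat$R, dat$mom, K, f)
  Tv <- su$T; Wv <- su$W
  llcore <- if (prior_only) 0 else memm_llcore(Tv, Wv, dat$mom, m, dat$gn)
  fprior <- function(f, lam, mu) {
    if (ptype == 0L) sum(dgamma(f, 1 / lam, scale = mu * lam, log = TRUE))
    else sum(dlnorm(f, log(mu) - log(1 + lam) / 2,
                    sqrt(log(1 + lam)), log = TRUE))
  }

  steps <- c(delta = 0.3, b = 0.3, m = 0.04, lam = 0.5, beta = 0.3,
             f = 0.8)
  acc <- win <- setNames(numeric(6), names(steps))
  acc_tot <- setNames(numeric(6), names(steps))
  n_tot <- setNames(numeric(6), names(steps))

  total <- burn_in + n_iter
  n_rec <- floor(n_iter / thin)
  chains <- matrix(NA_real_, n_rec, 6 + nbeta)
  colnames(chains) <- c("delta", "b", "m", "dispersion", "d_ratio",
                        "loglik",
                        if (nbeta) paste0("beta_", lev[-1]) else NULL)
  f_draws <- matrix(NA_real_, n_rec, nj)
  colnames(f_draws) <- dat$males
  rec <- 0L
  ll_sum <- 0; ll_n <- 0L

  bump <- function(name, hit) {
    acc[name] <<- acc[name] + hit
    win[name] <<- win[name] + 1
    acc_tot[name] <<- acc_tot[name] + hit
    n_tot[name] <<- n_tot[name] + 1
  }

  for (it in seq_len(total)) {
    ## --- kernel scale delta (log random walk, uniform prior on delta)
    ld_new <- log(delta) + rnorm(1, 0, steps["delta"])
    hit <- 0
    if (exp(ld_new) >= prior$delta[1] && exp(ld_new) <= prior$delta[2]) {
      Kn <- memm_kernel(D, exp(ld_new), b)
      sn <- memm_sums(dat$R, dat$mom, Kn, f)
      lln <- if (prior_only) 0 else memm_llcore(sn$T, sn$W, dat$mom, m, dat$gn)
      if (log(runif(1)) < (lln - llcore) + (ld_new - log(delta))) {
        delta <- exp(ld_new); K <- Kn; Tv <- sn$T; Wv <- sn$W
        llcore <- lln; hit <- 1
      }
    }
    bump("delta", hit)

    ## --- kernel shape b
    lb_new <- log(b) + rnorm(1, 0, steps["b"])
    hit <- 0
    if (exp(lb_new) >= prior$b[1] && exp(lb_new) <= prior$b[2]) {
      Kn <- memm_kernel(D, delta, exp(lb_new))
      sn <- memm_sums(dat$R, dat$mom, Kn, f)
      lln <- if (prior_only) 0 else memm_llcore(sn$T, sn$W, dat$mom, m, dat$gn)
      if (log(runif(1)) < (lln - llcore) + (lb_new - log(b))) {
        b <- exp(lb_new); K <- Kn; Tv <- sn$T; Wv <- sn$W
        llcore <- lln; hit <- 1
      }
    }
    bump("b", hit)

    ## --- immigration rate m (natural scale, cached mating sums)
    m_new <- m + rnorm(1, 0, steps["m"])
    hit <- 0
    if (m_new >= prior$m[1] && m_new <= prior$m[2]) {
      lln <- if (prior_only) 0 else memm_llcore(Tv, Wv, dat$mom, m_new, dat$gn)
      if (log(runif(1)) < lln - llcore) {
        m <- m_new; llcore <- lln; hit <- 1
      }
    }
    bump("m", hit)

    ## --- fecundity dispersion (prior-level update; likelihood unchanged)
    ll_lam <- log(lam) + rnorm(1, 0, steps["lam"])
    hit <- 0
    if (1 + exp(ll_lam) >= prior$ratio[1] &&
        1 + exp(ll_lam) <= prior$ratio[2]) {
      dp <- fprior(f, exp(ll_lam), mu) - fprior(f, lam, mu)
      if (log(runif(1)) < dp + (ll_lam - log(lam))) {
        lam <- exp(ll_lam); hit <- 1
      }
    }
    bump("lam", hit)

    ## --- covariate effects on expected fecundity
    if (nbeta) {
      hitb <- 0
      for (kk in seq_len(nbeta)) {
        bn <- beta; bn[kk] <- bn[kk] + rnorm(1, 0, steps["beta"])
        mun <- exp(as.numeric(X %*% bn))
        dp <- fprior(f, lam, mun) - fprior(f, lam, mu)
        if (log(runif(1)) < dp) {
          beta <- bn; mu <- mun; hitb <- hitb + 1
        }
      }
      bump("beta", hitb / nbeta)
    }

    ## --- per-male fecundities (C++ sweep, incremental sums)
    sw <- memm_fec_sweep(dat$R, dat$mom, K, f, Tv, Wv, dat$gn, m,
                         steps["f"], ptype, ppar(lam), mu, prior_only)
    f <- sw$f; Tv <- sw$T; Wv <- sw$W
    llcore <- if (prior_only) 0 else memm_llcore(Tv, Wv, dat$mom, m, dat$gn)
    bump("f", sw$accept / nj)

    ## --- step-size adaptation, burn-in only
    if (it <= burn_in && it %% 100 == 0) {
      rate <- acc / pmax(win, 1)
      steps <- steps * exp(0.2 * (rate - 0.3))
      steps["m"] <- min(steps["m"], 0.25)
      acc[] <- 0; win[] <- 0
    }

    if (it > burn_in) {
      ll_sum <- ll_sum + (llcore + const_ll)
      ll_n <- ll_n + 1L
      if ((it - burn_in) %% thin == 0 && rec < n_rec) {
        rec <- rec + 1L
        fn <- f / mean(f)
        chains[rec, ] <- c(delta, b, m, lam,
                           nj * sum(fn^2) / sum(fn)^2,
                           llcore + const_ll, beta)
        f_draws[rec, ] <- fn
      }
      if (verbose && (it - burn_in) %% 5000 == 0)
        message(sprintf("iter %d: delta=%.0f b=%.2f m=%.3f logL=%.1f",
                        it - burn_in, delta, b, m, llcore + const_ll))
    }
  }

  chains <- as.data.frame(chains[seq_len(rec), , drop = FALSE])
  f_draws <- f_draws[seq_len(rec), , drop = FALSE]
  qs <- function(v) c(mean = mean(v), lo = unname(quantile(v, 0.025)),
                      hi = unname(quantile(v, 0.975)))
  summ <- t(vapply(chains[setdiff(names(chains), "loglik")], qs,
                   numeric(3)))
  acc_rate <- (acc_tot / pmax(n_tot, 1))[n_tot > 0]
  structure(list(
    chains = chains, f_draws = f_draws, summary = summ,
    mean_loglik = if (ll_n) ll_sum / ll_n else NA_real_,
    acceptance = acc_rate, steps = steps,
    prior = prior, fecundity = fecundity, covariate_levels = lev,
    males = dat$males, n_seeds = nrow(dat$R),
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    prior_only = prior_only),
    class = "memm_fit")
}

#' @export
print.memm_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed-effect mating model (%s fecundities%s): %d seeds, %d males\n",
    x$fecundity, if (x$prior_only) ", prior only" else "",
    x$n_seeds, length(x$males)))
  cat(sprintf("%d iterations after %d burn-in (thin %d)\n",
              x$n_iter, x$burn_in, x$thin))
  s <- x$summary
  for (nm in c("delta", "b", "m", "d_ratio"))
    cat(sprintf("  %-8s %8.3g  (95%% CI %.3g-%.3g)\n", nm,
                s[nm, "mean"], s[nm, "lo"], s[nm, "hi"]))
  cat(sprintf("mean conditional log-likelihood: %.1f\n", x$mean_loglik))
  invisible(x)
}

#' @export
summary.memm_fit <- function(object, ...) object$summary

#' @export
coef.memm_fit <- function(object, ...) {
  object$summary[c("delta", "b", "m", "d_ratio"), "mean"]
}

#' @export
plot.memm_fit <- function(x, pars = c("delta", "b", "m"), ...) {
  op <- par(mfrow = c(length(pars), 1), mar = c(3, 4, 1, 1))
  on.exit(par(op))
  for (p in pars)
    plot(x$chains[[p]], type = "l", ylab = p, xlab = "", ...)
  invisible(x)
}

## low-acceptance diagnostics are reported rather than silently ignored
#' Check MCMC acceptance rates
#' @param fit a `memm_fit`.
#' @return Invisibly, the acceptance-rate vector; warns when any rate is
#'   below 1% or above 99%.
#' @export
memm_check <- function(fit) {
  r <- fit$acceptance
  if (any(r < 0.01 | r > 0.99))
    warning("extreme acceptance rate(s): ",
            paste(sprintf("%s=%.3f", names(r), r), collapse = ", "))
  invisible(r)
}

#' Approximate Bayes factor between two mating-model fits
#'
#' Computed as the ratio of the estimated likelihoods,
#' `exp(meanlogL_A - meanlogL_B)`, using the mean conditional
#' log-likelihood over post-burn-in draws of each fit on identical data.
#'
#' @param fit_a,fit_b `memm_fit` objects fitted to the same data.
#' @return The Bayes factor of model A over model B.
#' @export
bayes_factor <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "memm_fit"), inherits(fit_b, "memm_fit"))
  if (fit_a$n_seeds != fit_b$n_seeds)
    stop("fits are not on identical data")
  exp(fit_a$mean_loglik - fit_b$mean_loglik)
}

#' Observed-to-effective male density ratio and effective father number
#'
#' From each posterior fecundity draw, the density ratio is
#' `N sum(f^2) / (sum f)^2` (one plus the squared coefficient of
#' variation of realised fecundities) and the effective number of pollen
#' donors is the observed male census divided by that ratio.
#'
#' @param fit a `memm_fit`.
#' @param n_obs observed census of males (defaults to the number of
#'   males in the fit).
#' @return List with posterior mean and 95% credibility intervals of
#'   `d_ratio` and `Nep`.
#' @export
effective_density_ratio <- function(fit, n_obs = NULL) {
  stopifnot(inherits(fit, "memm_fit"))
  if (is.null(n_obs)) n_obs <- length(fit$males)
  fd <- fit$f_draws
  ratio <- ncol(fd) * rowSums(fd^2) / rowSums(fd)^2
  nep <- n_obs / ratio
  qs <- function(v) c(mean = mean(v), lo = unname(quantile(v, 0.025)),
                      hi = unname(quantile(v, 0.975)))
  list(d_ratio = qs(ratio), Nep = qs(nep))
}
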