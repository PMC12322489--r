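# MCMC engine for the hierarchical models.
#
# Two samplers, one per family, both targeting the exact posterior of a
# random-intercept model with weakly informative priors:
#
# * gaussian: the random intercepts are integrated out analytically
#   (each group's covariance is sigma^2 I + tau^2 J, inverted in closed
#   form), the fixed effects are drawn from their conjugate GLS
#   conditional, and (log sigma, log tau) are updated by univariate slice
#   sampling on the marginal posterior. Marginalisation removes the
#   funnel between the intercepts and tau, which matters for designs with
#   a single observation per group. Intercepts are re-drawn from their
#   exact conditional for storage.
#
# * bernoulli-logit: the fixed-effect block is updated by an
#   independence Metropolis-Hastings step whose proposal is the Laplace
#   approximation of the conditional posterior (recomputed each
#   iteration; the conditional is log-concave so Newton is reliable);
#   random intercepts are updated jointly by vectorised per-group
#   Laplace-proposal MH (the conditional factorises over groups); tau by
#   slice sampling. Acceptance rates are high and draws nearly
#   independent, so the default run lengths reach the effective sample
#   sizes required by the convergence gates.

# numerically stable log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  small <- x < 18
  out[small] <- log1p(exp(x[small]))
  big <- x >= 18 & x < 34
  out[big] <- x[big] + exp(-x[big])
  out
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
.slice1 <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  y <- f0 + log(stats::runif(1)) # slice level below the current density
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(lo) > y) {
    lo <- lo - w
    j <- j - 1
  }
  while (k > 0 && logf(hi) > y) {
    hi <- hi + w
    k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# marginal log-likelihood of a gaussian random-intercept model
# (intercepts integrated out), plus helpers shared by the draws
.gauss_marg_ll <- function(resid, grp, ng, sigma2, tau2) {
  S <- rowsum(resid, grp)[, 1]
  SS <- sum(resid^2)
  den <- sigma2 + ng * tau2
  -0.5 * (sum((ng - 1) * log(sigma2) + log(den)) +
            (SS - sum(tau2 * S^2 / den)) / sigma2)
}

.fit_gaussian <- function(y, X, grp, prior, chains, iterations, warmup, seed) {
  n <- length(y)
  p <- ncol(X)
  G <- max(grp)
  ng <- tabulate(grp, G)
  Xg <- rowsum(X, grp) # G x p group sums
  yg <- rowsum(y, grp)[, 1]
  # within-group-centred parts: the GLS precision decomposes as
  # Xc'Xc/sigma^2 + sum_g Xg Xg' / (n_g (sigma^2 + n_g tau^2)) + prior,
  # a sum of PSD terms with no cancellation even as sigma -> 0
  Xc <- X - (Xg / ng)[grp, , drop = FALSE]
  yc <- y - (yg / ng)[grp]
  XcTXc <- crossprod(Xc)
  XcTyc <- crossprod(Xc, yc)[, 1]

  kept <- iterations - warmup
  npar <- p + 2 + G
  draws <- array(NA_real_, c(kept, npar, chains))

  ols <- stats::lm.fit(X, y)
  sd_res <- stats::sd(ols$residuals)
  if (!is.finite(sd_res) || sd_res <= 0) sd_res <- stats::sd(y)
  if (!is.finite(sd_res) || sd_res <= 0) sd_res <- 1

  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    beta <- ols$coefficients + stats::rnorm(p, 0, 0.1 * sd_res / sqrt(n))
    beta[!is.finite(beta)] <- 0
    log_sigma <- log(sd_res) + stats::rnorm(1, 0, 0.2)
    log_tau <- log(sd_res * 0.5) + stats::rnorm(1, 0, 0.5)
    floor_ls <- log(max(sd_res, 1e-3)) - 9
    for (it in seq_len(iterations)) {
      resid <- y - drop(X %*% beta)
      lp_sigma <- function(ls) {
        s2 <- exp(2 * ls)
        .gauss_marg_ll(resid, grp, ng, s2, exp(2 * log_tau)) -
          prior$sigma_rate * exp(ls) + ls
      }
      log_sigma <- max(.slice1(log_sigma, lp_sigma, w = 0.5), floor_ls)
      lp_tau <- function(lt) {
        t2 <- exp(2 * lt)
        .gauss_marg_ll(resid, grp, ng, exp(2 * log_sigma), t2) -
          exp(2 * lt) / (2 * prior$tau_scale^2) + lt
      }
      log_tau <- max(.slice1(log_tau, lp_tau, w = 0.5), floor_ls)
      # rotated slice along (log sigma up, log tau down): moves along the
      # sigma^2 + tau^2 ridge left by designs with one observation per
      # group, where the two scales are only jointly identified
      ls0 <- log_sigma
      lt0 <- log_tau
      lp_rot <- function(d) {
        .gauss_marg_ll(resid, grp, ng, exp(2 * (ls0 + d)), exp(2 * (lt0 - d))) -
          prior$sigma_rate * exp(ls0 + d) + (ls0 + d) -
          exp(2 * (lt0 - d)) / (2 * prior$tau_scale^2) + (lt0 - d)
      }
      d <- .slice1(0, lp_rot, w = 0.5)
      # the floor keeps degenerate (constant) responses from collapsing
      # the scales to numerical zero
      log_sigma <- max(ls0 + d, floor_ls)
      log_tau <- max(lt0 - d, floor_ls)
      sigma2 <- exp(2 * log_sigma)
      tau2 <- exp(2 * log_tau)
      # conjugate GLS draw of beta given (sigma, tau), intercepts out
      v_g <- 1 / (ng * (sigma2 + ng * tau2))
      P <- XcTXc / sigma2 + crossprod(Xg * sqrt(v_g)) +
        diag(1 / prior$beta_scale^2, p)
      bvec <- XcTyc / sigma2 + crossprod(Xg, v_g * yg)[, 1] +
        prior$beta_location / prior$beta_scale^2
      R <- chol(P)
      m <- backsolve(R, backsolve(R, bvec, transpose = TRUE))
      beta <- m + backsolve(R, stats::rnorm(p))
      if (it > warmup) {
        # exact conditional draw of the intercepts for storage/PPC
        resid <- y - drop(X %*% beta)
        S <- rowsum(resid, grp)[, 1]
        v <- 1 / (ng / sigma2 + 1 / tau2)
        u <- stats::rnorm(G, v * S / sigma2, sqrt(v))
        draws[it - warmup, , ch] <- c(beta, exp(log_sigma), exp(log_tau), u)
      }
    }
  }
  draws
}

.fit_logit <- function(y, X, grp, prior, chains, iterations, warmup, seed,
                       shift_idx = rep(FALSE, ncol(X))) {
  n <- length(y)
  p <- ncol(X)
  G <- max(grp)
  ng <- tabulate(grp, G)
  kept <- iterations - warmup
  npar <- p + 1 + G
  draws <- array(NA_real_, c(kept, npar, chains))

  loglik_beta <- function(beta, u) {
    eta <- drop(X %*% beta) + u[grp]
    sum(y * eta - .log1pexp(eta)) -
      sum((beta - prior$beta_location)^2 / (2 * prior$beta_scale^2))
  }

  init <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  init[!is.finite(init)] <- 0
  init <- pmin(pmax(init, -8), 8)

  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    beta <- init + stats::rnorm(p, 0, 0.1)
    u <- rep(0, G)
    log_tau <- stats::rnorm(1, log(0.5), 0.3)
    reinit <- 0
    while (!is.finite(loglik_beta(beta, u)) && reinit < 10) {
      beta <- stats::rnorm(p, 0, 0.5)
      reinit <- reinit + 1
    }
    if (!is.finite(loglik_beta(beta, u))) {
      stop("logit sampler: could not find a finite starting point")
    }
    for (it in seq_len(iterations)) {
      for (cyc in 1:2) { # two full update cycles per stored iteration
      tau2 <- exp(2 * log_tau)
      # -- fixed effects: Laplace-approximation independence MH
      bhat <- beta
      for (nr in 1:4) {
        eta <- drop(X %*% bhat) + u[grp]
        mu <- stats::plogis(eta)
        gr <- crossprod(X, y - mu)[, 1] - (bhat - prior$beta_location) / prior$beta_scale^2
        H <- crossprod(X * (mu * (1 - mu)), X) + diag(1 / prior$beta_scale^2, p)
        step <- solve(H, gr)
        bhat <- bhat + step
        if (max(abs(step)) < 1e-8) break
      }
      R <- chol(H)
      prop <- bhat + backsolve(R, stats::rnorm(p))
      # log proposal densities under N(bhat, H^-1)
      qf <- function(b) -0.5 * sum((R %*% (b - bhat))^2)
      la <- loglik_beta(prop, u) - loglik_beta(beta, u) + qf(beta) - qf(prop)
      if (is.finite(la) && log(stats::runif(1)) < la) beta <- prop
      # -- random intercepts: vectorised per-group Laplace MH
      eta_fix <- drop(X %*% beta)
      uhat <- u
      for (nr in 1:3) {
        mu <- stats::plogis(eta_fix + uhat[grp])
        gr_g <- rowsum(y - mu, grp)[, 1] - uhat / tau2
        h_g <- rowsum(mu * (1 - mu), grp)[, 1] + 1 / tau2
        uhat <- uhat + gr_g / h_g
      }
      sd_g <- 1 / sqrt(h_g)
      uprop <- uhat + sd_g * stats::rnorm(G)
      llg <- function(uv) {
        mu_eta <- eta_fix + uv[grp]
        rowsum(y * mu_eta - .log1pexp(mu_eta), grp)[, 1] - uv^2 / (2 * tau2)
      }
      la_g <- llg(uprop) - llg(u) +
        0.5 * ((uprop - uhat)^2 - (u - uhat)^2) / sd_g^2
      acc <- log(stats::runif(G)) < la_g
      u[acc] <- uprop[acc]
      # -- tau: slice on log scale
      lp_tau <- function(lt) {
        t2 <- exp(2 * lt)
        -G * lt - sum(u^2) / (2 * t2) - exp(2 * lt) / (2 * prior$tau_scale^2) + lt
      }
      log_tau <- .slice1(log_tau, lp_tau, w = 0.7)
      tau2 <- exp(2 * log_tau)
      # -- recentering move: trade a shift d between the intercept-like
      # fixed effects and all random intercepts (likelihood-invariant)
      if (any(shift_idx)) {
        d <- stats::rnorm(1, 0, 0.5 * exp(log_tau) + 0.05)
        la <- sum(stats::dnorm(u - d, 0, exp(log_tau), log = TRUE)) -
          sum(stats::dnorm(u, 0, exp(log_tau), log = TRUE)) +
          sum(stats::dnorm(beta[shift_idx] + d, prior$beta_location[shift_idx],
                           prior$beta_scale[shift_idx], log = TRUE)) -
          sum(stats::dnorm(beta[shift_idx], prior$beta_location[shift_idx],
                           prior$beta_scale[shift_idx], log = TRUE))
        if (is.finite(la) && log(stats::runif(1)) < la) {
          u <- u - d
          beta[shift_idx] <- beta[shift_idx] + d
        }
      }
      # -- joint (tau, u) move: random-walk proposal on log tau with the
      # intercepts refreshed from their tau-conditional Laplace proposal
      # (Newton from zero, so the proposal depends only on beta and tau);
      # this breaks the tau <-> |u| coupling that throttles mixing when
      # groups carry little information each
      eta_fix <- drop(X %*% beta)
      lap <- function(t2loc) {
        uh <- rep(0, G)
        h_g <- NULL
        for (nr in 1:4) {
          mu <- stats::plogis(eta_fix + uh[grp])
          gr_g <- rowsum(y - mu, grp)[, 1] - uh / t2loc
          h_g <- rowsum(mu * (1 - mu), grp)[, 1] + 1 / t2loc
          uh <- uh + gr_g / h_g
        }
        list(m = uh, s = 1 / sqrt(h_g))
      }
      prior_lt <- function(lt) -exp(2 * lt) / (2 * prior$tau_scale^2) + lt
      ll_u <- function(uv) {
        eta <- eta_fix + uv[grp]
        sum(y * eta - .log1pexp(eta))
      }
      # mix short and long proposals: the long ones traverse wide,
      # prior-dominated tau posteriors (single-observation groups)
      lt_prop <- log_tau + stats::rnorm(1, 0, sample(c(0.3, 1), 1))
      lap_cur <- lap(exp(2 * log_tau))
      lap_prp <- lap(exp(2 * lt_prop))
      u_prop <- lap_prp$m + lap_prp$s * stats::rnorm(G)
      la <- (ll_u(u_prop) + sum(stats::dnorm(u_prop, 0, exp(lt_prop), log = TRUE)) +
               prior_lt(lt_prop) +
               sum(stats::dnorm(u, lap_cur$m, lap_cur$s, log = TRUE))) -
        (ll_u(u) + sum(stats::dnorm(u, 0, exp(log_tau), log = TRUE)) +
           prior_lt(log_tau) +
           sum(stats::dnorm(u_prop, lap_prp$m, lap_prp$s, log = TRUE)))
      if (is.finite(la) && log(stats::runif(1)) < la) {
        u <- u_prop
        log_tau <- lt_prop
      }
      # -- scale move along the (tau, u) funnel: (tau, u) -> (c tau, c u)
      lc <- stats::rnorm(1, 0, 0.4)
      cc <- exp(lc)
      eta0 <- drop(X %*% beta)
      ll_u <- function(uv) sum(y * (eta0 + uv[grp]) - .log1pexp(eta0 + uv[grp]))
      lt_new <- log_tau + lc
      # the intercept-prior c^-G factor cancels the Jacobian c^G exactly
      la <- ll_u(cc * u) - ll_u(u) +
        (-exp(2 * lt_new) / (2 * prior$tau_scale^2) + lt_new) -
        (-exp(2 * log_tau) / (2 * prior$tau_scale^2) + log_tau)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        u <- cc * u
        log_tau <- lt_new
      }
      } # end update cycles
      if (it > warmup) {
        draws[it - warmup, , ch] <- c(beta, exp(log_tau), u)
      }
    }
  }
  draws
}
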