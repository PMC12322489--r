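#' Model specifications for the foraging-condition analysis
#'
#' Four hierarchical models, all with an individual (bird) random
#' intercept:
#' \describe{
#'   \item{M1_logrange}{log(maximum range) ~ year + colony, gaussian;
#'     treatment contrasts with the reference year and colony as
#'     baseline. Fitted separately to inside- and outside-fjord trips.}
#'   \item{M2_outside}{outside (0/1 per trip) ~ year + colony,
#'     bernoulli-logit, treatment contrasts.}
#'   \item{M3_firsttrip}{first trip after release outside (0/1 per bird)
#'     ~ body condition + year indicators + colony, bernoulli-logit.
#'     Year enters as one indicator per year with no global intercept
#'     (cell-means coding): the printed formulation carries an intercept
#'     plus all three indicators, which is over-parameterised, so the
#'     intercept column is dropped.}
#'   \item{M4_bmc}{relative body-mass change (per bird) ~ outside-trip
#'     proportion + year indicators + colony, gaussian, cell-means year
#'     coding as in M3.}
#' }
#'
#' @param name One of \code{"M1_logrange"}, \code{"M2_outside"},
#'   \code{"M3_firsttrip"}, \code{"M4_bmc"}.
#' @param ref_year Reference year for treatment contrasts (default:
#'   smallest year in the data).
#' @param ref_colony Reference colony (default: first level
#'   alphabetically).
#' @return Object of class \code{cpf_model_spec}.
#' @export
model_spec <- function(name = c("M1_logrange", "M2_outside", "M3_firsttrip", "M4_bmc"),
                       ref_year = NULL, ref_colony = NULL) {
  name <- match.arg(name)
  family <- if (name %in% c("M1_logrange", "M4_bmc")) "gaussian" else "binomial"
  structure(list(name = name, family = family,
                 ref_year = ref_year, ref_colony = ref_colony),
            class = "cpf_model_spec")
}

#' Build response, design matrix and grouping for a model
#'
#' @param spec A \code{cpf_model_spec} (or model name).
#' @param data For M1/M2: a trip table (one row per trip) with
#'   \code{bird_id}, \code{year}, \code{colony_id}, \code{max_range_km},
#'   \code{label}. For M3/M4: a condition table (one row per bird) with
#'   \code{bird_id}, \code{year}, \code{colony_id}, \code{bc},
#'   \code{prop_outside}, \code{bmc}, \code{first_outside}.
#' @return List with \code{y}, \code{X} (named columns), \code{grp}
#'   (integer group index), \code{grp_levels} (bird ids), \code{family},
#'   \code{spec}, and the factor levels used (for prediction rows).
#' @export
build_design <- function(spec, data) {
  if (is.character(spec)) spec <- model_spec(spec)
  data <- as.data.frame(data)
  years <- sort(unique(data$year))
  colonies <- sort(unique(as.character(data$colony_id)))
  ref_year <- if (is.null(spec$ref_year)) years[1] else spec$ref_year
  ref_colony <- if (is.null(spec$ref_colony)) colonies[1] else spec$ref_colony
  if (!(ref_year %in% years)) stop("build_design: reference year absent from data")
  if (!(ref_colony %in% colonies)) stop("build_design: reference colony absent from data")

  year_contrast_cols <- function() {
    out <- NULL
    for (yr in setdiff(years, ref_year)) {
      out <- cbind(out, as.numeric(data$year == yr))
      colnames(out)[ncol(out)] <- paste0("year", yr)
    }
    out
  }
  year_indicator_cols <- function() {
    out <- NULL
    for (yr in years) {
      out <- cbind(out, as.numeric(data$year == yr))
      colnames(out)[ncol(out)] <- paste0("I.year", yr)
    }
    out
  }
  colony_cols <- function() {
    out <- NULL
    for (cl in setdiff(colonies, ref_colony)) {
      out <- cbind(out, as.numeric(as.character(data$colony_id) == cl))
      colnames(out)[ncol(out)] <- paste0("colony", cl)
    }
    out
  }

  nm <- spec$name
  if (nm == "M1_logrange") {
    if (any(data$max_range_km <= 0)) stop("build_design: non-positive ranges")
    y <- log(data$max_range_km)
    X <- cbind(`(Intercept)` = 1, year_contrast_cols(), colony_cols())
    intercept_like <- c(TRUE, rep(FALSE, ncol(X) - 1))
  } else if (nm == "M2_outside") {
    y <- as.numeric(data$label == "outside")
    X <- cbind(`(Intercept)` = 1, year_contrast_cols(), colony_cols())
    intercept_like <- c(TRUE, rep(FALSE, ncol(X) - 1))
  } else if (nm == "M3_firsttrip") {
    y <- as.numeric(data$first_outside == "outside")
    X <- cbind(bc = data$bc, year_indicator_cols(), colony_cols())
    intercept_like <- c(FALSE, rep(TRUE, length(years)),
                        rep(FALSE, length(colonies) - 1))
  } else { # M4_bmc
    y <- data$bmc
    X <- cbind(prop = data$prop_outside, year_indicator_cols(), colony_cols())
    intercept_like <- c(FALSE, rep(TRUE, length(years)),
                        rep(FALSE, length(colonies) - 1))
  }
  ok <- stats::complete.cases(cbind(y, X))
  if (!all(ok)) {
    y <- y[ok]
    X <- X[ok, , drop = FALSE]
    data <- data[ok, , drop = FALSE]
  }
  grp_levels <- sort(unique(as.character(data$bird_id)))
  grp <- match(as.character(data$bird_id), grp_levels)
  if (length(y) < ncol(X) + 2) stop("build_design: too few observations for the design")
  list(y = y, X = X, grp = grp, grp_levels = grp_levels,
       family = spec$family, spec = spec, years = years, colonies = colonies,
       ref_year = ref_year, ref_colony = ref_colony,
       intercept_like = intercept_like)
}

# weakly informative auto-scaled priors (rstanarm-style conventions):
# slopes N(0, 2.5 sd(y)/sd(x)) for gaussian, N(0, 2.5/sd(x)) for logit;
# intercept-like columns get the unscaled-x version; sigma ~
# Exponential(1/sd(y)); random-intercept sd half-normal.
default_priors <- function(design) {
  X <- design$X
  p <- ncol(X)
  sdx <- apply(X, 2, stats::sd)
  sdx[sdx == 0 | design$intercept_like] <- 1
  if (design$family == "gaussian") {
    sdy <- stats::sd(design$y)
    if (!is.finite(sdy) || sdy == 0) sdy <- 1
    loc <- ifelse(design$intercept_like, mean(design$y), 0)
    list(beta_location = loc,
         beta_scale = 2.5 * sdy / sdx,
         sigma_rate = 1 / sdy,
         tau_scale = 2.5 * sdy)
  } else {
    list(beta_location = rep(0, p),
         beta_scale = 2.5 / sdx,
         sigma_rate = NA_real_,
         tau_scale = 2.5)
  }
}

#' Fit a hierarchical model by MCMC
#'
#' Runs the family-appropriate sampler (see the engine notes in the
#' package source): exact-conditional Gibbs with marginalised intercepts
#' for gaussian responses, Laplace-proposal Metropolis-within-Gibbs for
#' bernoulli-logit responses. Chains are run sequentially with seeds
#' \code{seed + 1, ..., seed + chains}; warmup draws are discarded.
#'
#' @param spec Model name or \code{cpf_model_spec}.
#' @param data Model data (see [build_design()]).
#' @param chains Number of chains (default 5).
#' @param iterations Iterations per chain (default 6000).
#' @param warmup Warmup iterations discarded (default 3000).
#' @param seed Integer seed.
#' @param priors Optional prior list (see \code{default_priors}).
#' @return Object of class \code{cpf_fit}: list with \code{draws}
#'   (array kept x parameter x chain), \code{par_names},
#'   \code{reported} (names of headline parameters), \code{design},
#'   \code{mcmc} settings.
#' @export
fit_model <- function(spec, data, chains = 5, iterations = 6000,
                      warmup = 3000, seed = 1, priors = NULL) {
  design <- build_design(spec, data)
  if (chains < 2) stop("fit_model: need at least 2 chains for diagnostics")
  if (warmup >= iterations) stop("fit_model: warmup must be < iterations")
  if (is.null(priors)) priors <- default_priors(design)
  G <- length(design$grp_levels)
  if (design$family == "gaussian") {
    draws <- .fit_gaussian(design$y, design$X, design$grp, priors,
                           chains, iterations, warmup, seed)
    par_names <- c(colnames(design$X), "sigma", "tau",
                   paste0("u[", design$grp_levels, "]"))
    reported <- c(colnames(design$X), "sigma", "tau")
  } else {
    draws <- .fit_logit(design$y, design$X, design$grp, priors,
                        chains, iterations, warmup, seed,
                        shift_idx = design$intercept_like)
    par_names <- c(colnames(design$X), "tau",
                   paste0("u[", design$grp_levels, "]"))
    reported <- c(colnames(design$X), "tau")
  }
  dimnames(draws) <- list(NULL, par_names, paste0("chain", seq_len(chains)))
  structure(list(draws = draws, par_names = par_names, reported = reported,
                 design = design, priors = priors,
                 mcmc = list(chains = chains, iterations = iterations,
                             warmup = warmup, seed = seed)),
            class = "cpf_fit")
}

#' @export
print.cpf_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s fit (%s): %d chains x %d kept draws, %d observations, %d individuals\n",
              x$design$spec$name, x$design$family, dim(x$draws)[3],
              dim(x$draws)[1], length(x$design$y), length(x$design$grp_levels)))
  s <- fit_summary(x)
  print(s$table, digits = 3)
  invisible(x)
}

# matrix of posterior draws (all chains pooled) for named parameters
.pooled_draws <- function(fit, pars = NULL) {
  d <- fit$draws
  if (is.null(pars)) pars <- fit$par_names
  idx <- match(pars, fit$par_names)
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) {
    matrix(d[, idx, ch], nrow = dim(d)[1], ncol = length(idx))
  }))
  colnames(out) <- pars
  out
}

#' Design row for a prediction cell
#'
#' Builds a single fixed-effect row matching the model's design matrix,
#' for back-transformed predictions and contrasts.
#'
#' @param fit A \code{cpf_fit}.
#' @param year Year of the cell.
#' @param colony_id Colony of the cell.
#' @param bc,prop Covariate values for M3/M4 (defaults 0).
#' @return Named numeric vector aligned with the design columns.
#' @export
prediction_row <- function(fit, year, colony_id, bc = 0, prop = 0) {
  design <- fit$design
  nm <- design$spec$name
  cols <- colnames(design$X)
  row <- stats::setNames(numeric(length(cols)), cols)
  if ("(Intercept)" %in% cols) row["(Intercept)"] <- 1
  yr_col <- paste0("year", year)
  if (yr_col %in% cols) row[yr_col] <- 1
  iyr_col <- paste0("I.year", year)
  if (iyr_col %in% cols) row[iyr_col] <- 1
  if (!(year %in% design$years)) stop("prediction_row: unseen year")
  cl_col <- paste0("colony", colony_id)
  if (cl_col %in% cols) row[cl_col] <- 1
  if (!(colony_id %in% design$colonies)) stop("prediction_row: unseen colony")
  if ("bc" %in% cols) row["bc"] <- bc
  if ("prop" %in% cols) row["prop"] <- prop
  if (nm %in% c("M1_logrange", "M2_outside")) {
    # treatment contrasts: reference cell has only the intercept active
  }
  row
}

# draws of the linear predictor for a design row (random intercept at its
# median, zero)
.linpred_draws <- function(fit, row) {
  b <- .pooled_draws(fit, colnames(fit$design$X))
  drop(b %*% row)
}

#' Back-transformed median prediction for a log-scale gaussian model
#'
#' For models fitted on log(response), the posterior draws of the linear
#' predictor are exponentiated; the result is the median of the response
#' distribution on the original scale (the lognormal median is
#' \eqn{e^{\mu}}), summarised by its posterior median and 95\% interval.
#'
#' @param fit A gaussian \code{cpf_fit} on a log response.
#' @param year,colony_id,bc,prop Cell definition, see [prediction_row()].
#' @return List with \code{median}, \code{pi_low}, \code{pi_high} (km).
#' @export
backtransform_median <- function(fit, year, colony_id, bc = 0, prop = 0) {
  if (fit$design$family != "gaussian") {
    stop("backtransform_median: only for gaussian (log-scale) models; ",
         "use inverse-logit predictions for binary models")
  }
  eta <- .linpred_draws(fit, prediction_row(fit, year, colony_id, bc, prop))
  resp <- exp(eta)
  qs <- stats::quantile(resp, c(0.5, 0.025, 0.975), names = FALSE)
  list(median = qs[1], pi_low = qs[2], pi_high = qs[3])
}

#' Posterior contrast between two prediction cells
#'
#' Distribution of the difference between two cells' predictions on the
#' reported scale (response km scale for log-gaussian models via
#' exponentiation, probability scale for logit models via the inverse
#' logit, linear scale otherwise), with the "evidence" convention that an
#' effect is supported when the 95\% interval excludes zero.
#'
#' @param fit A \code{cpf_fit}.
#' @param cell_a,cell_b Lists of arguments for [prediction_row()]
#'   (\code{year}, \code{colony_id}, optionally \code{bc}, \code{prop}).
#' @param scale \code{"response"} (default) or \code{"link"}.
#' @return List with \code{mean}, \code{pi_low}, \code{pi_high},
#'   \code{evidence}.
#' @export
contrast_cells <- function(fit, cell_a, cell_b, scale = c("response", "link")) {
  scale <- match.arg(scale)
  ra <- do.call(prediction_row, c(list(fit), cell_a))
  rb <- do.call(prediction_row, c(list(fit), cell_b))
  ea <- .linpred_draws(fit, ra)
  eb <- .linpred_draws(fit, rb)
  if (scale == "response") {
    if (fit$design$family == "gaussian" && fit$design$spec$name == "M1_logrange") {
      ea <- exp(ea)
      eb <- exp(eb)
    } else if (fit$design$family == "binomial") {
      ea <- stats::plogis(ea)
      eb <- stats::plogis(eb)
    }
  }
  diff <- ea - eb
  qs <- stats::quantile(diff, c(0.025, 0.975), names = FALSE)
  list(mean = mean(diff), pi_low = qs[1], pi_high = qs[2],
       evidence = qs[1] > 0 || qs[2] < 0)
}

#' Posterior predictive check
#'
#' Simulates replicate response vectors from a subset of posterior draws
#' (fixed effects, random intercepts and, for gaussian models, the
#' residual scale) and compares summary statistics of the replicates with
#' the observed data. Tail probabilities near 0 or 1 flag summaries the
#' model fails to reproduce.
#'
#' @param fit A \code{cpf_fit}.
#' @param n_rep Number of posterior draws to simulate from (default 200).
#' @param seed Integer seed.
#' @return Data frame with one row per summary statistic: observed value,
#'   replicate mean, and \code{p_lower} = P(replicate <= observed).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1) {
  design <- fit$design
  X <- design$X
  grp <- design$grp
  y <- design$y
  d <- .pooled_draws(fit)
  n_draws <- nrow(d)
  take <- round(seq(1, n_draws, length.out = min(n_rep, n_draws)))
  bcols <- match(colnames(X), fit$par_names)
  ucols <- match(paste0("u[", design$grp_levels, "]"), fit$par_names)
  stats_fun <- if (design$family == "binomial") {
    function(v) c(mean = mean(v), sd = stats::sd(v), prop = mean(v))
  } else {
    function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  }
  obs <- stats_fun(y)
  reps <- with_seed(seed, {
    t(vapply(take, function(i) {
      eta <- drop(X %*% d[i, bcols]) + d[i, ucols][grp]
      yrep <- if (design$family == "binomial") {
        stats::rbinom(length(eta), 1, stats::plogis(eta))
      } else {
        stats::rnorm(length(eta), eta, d[i, match("sigma", fit$par_names)])
      }
      stats_fun(yrep)
    }, obs))
  })
  data.frame(statistic = names(obs),
             observed = unname(obs),
             replicated_mean = colMeans(reps),
             p_lower = vapply(seq_along(obs), function(j) mean(reps[, j] <= obs[j]),
                              numeric(1)),
             row.names = NULL)
}
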