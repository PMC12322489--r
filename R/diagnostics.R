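#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half; R-hat is the square root of the ratio of
#' the weighted between/within variance estimate to the pooled
#' within-chain variance across the split chains. Values near 1 indicate
#' the chains agree; values above ~1.1 indicate non-convergence.
#'
#' @param m Matrix of draws, iterations x chains (one parameter).
#' @return R-hat (scalar).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("split_rhat: need at least 2 chains")
  n <- nrow(m)
  half <- floor(n / 2)
  sub <- cbind(m[1:half, , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  nn <- nrow(sub)
  mu <- colMeans(sub)
  W <- mean(apply(sub, 2, stats::var))
  B <- nn * stats::var(mu)
  if (W == 0) return(1)
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

#' Effective sample size across chains
#'
#' Autocorrelation-adjusted effective number of draws, combining
#' within-chain autocovariances with the between-chain variance and
#' truncating the autocorrelation sum by Geyer's initial monotone
#' positive sequence.
#'
#' @param m Matrix of draws, iterations x chains (one parameter).
#' @return Effective sample size (scalar).
#' @export
ess <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  nch <- ncol(m)
  if (n < 4) return(NA_real_)
  mu <- colMeans(m)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) return(NA_real_)
  B_over_n <- if (nch > 1) stats::var(mu) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  max_lag <- min(n - 1, 10 * floor(sqrt(n)))
  # mean autocovariance across chains per lag
  acov <- matrix(0, max_lag + 1, nch)
  for (ch in seq_len(nch)) {
    a <- stats::acf(m[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acov[, ch] <- a
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decay
  npairs <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(npairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  n * nch / tau
}

#' Convergence and summary table for a fitted model
#'
#' Posterior mean, 95\% interval, split R-hat and effective sample size
#' for the reported parameters (fixed effects and variance components);
#' the fit is flagged converged when every R-hat is below
#' \code{rhat_max} and every effective sample size exceeds
#' \code{neff_min}.
#'
#' @param fit A \code{cpf_fit}.
#' @param rhat_max R-hat threshold (default 1.1).
#' @param neff_min Effective-sample-size threshold (default 1000).
#' @return Object of class \code{cpf_summary}: list with \code{table}
#'   (data frame) and \code{convergence_ok}.
#' @export
fit_summary <- function(fit, rhat_max = 1.1, neff_min = 1000) {
  pars <- fit$reported
  idx <- match(pars, fit$par_names)
  tab <- do.call(rbind, lapply(seq_along(pars), function(j) {
    m <- fit$draws[, idx[j], ]
    pooled <- as.numeric(m)
    qs <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = pars[j],
               mean = mean(pooled),
               pi_low = qs[1],
               pi_high = qs[2],
               rhat = split_rhat(m),
               neff = ess(m),
               stringsAsFactors = FALSE)
  }))
  ok <- all(tab$rhat < rhat_max, na.rm = FALSE) &&
    all(tab$neff > neff_min, na.rm = FALSE)
  structure(list(table = tab, convergence_ok = ok,
                 rhat_max = rhat_max, neff_min = neff_min),
            class = "cpf_summary")
}

#' @export
print.cpf_summary <- function(x, ...) {
  print(x$table, digits = 3)
  cat(if (x$convergence_ok) "Converged" else "NOT converged",
      sprintf("(gates: R-hat < %s, Neff > %s)\n", x$rhat_max, x$neff_min))
  invisible(x)
}
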