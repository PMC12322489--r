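#' Count modes of a Gaussian kernel density estimate
#'
#' Evaluates the KDE on an equally spaced grid over \code{limits} and
#' counts interior local maxima; maxima at the grid endpoints are not
#' counted, so spurious boundary modes (e.g. in the right tail beyond the
#' window) are ignored.
#'
#' @param values Numeric sample.
#' @param bw Gaussian kernel bandwidth (same units as \code{values}).
#' @param limits Length-2 numeric: evaluation window.
#' @param n_grid Grid size (default 512).
#' @return List with \code{k} (number of modes) and \code{modes} (their
#'   grid locations, ascending).
#' @export
kde_modes <- function(values, bw, limits, n_grid = 512) {
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = limits[1], to = limits[2], n = n_grid)
  y <- d$y
  dy <- diff(y)
  s <- ifelse(dy > 0, 1L, -1L)
  # interior indices where the estimate switches from rising to falling;
  # floating-point ripple in regions of negligible density is not a mode
  idx <- which(s[-length(s)] == 1L & s[-1L] == -1L) + 1L
  idx <- idx[y[idx] > 1e-9 * max(y)]
  list(k = length(idx), modes = d$x[idx])
}

#' Critical bandwidth for a target number of modes
#'
#' The smallest Gaussian-kernel bandwidth at which the kernel density
#' estimate, evaluated on a 512-point grid over \code{limits}, has at most
#' \code{k_target} local maxima. Mode counting is restricted to the window
#' so that artificial modes in the far right tail do not inflate the
#' count. Found by bisection.
#'
#' @param values Numeric sample (n >= 3, not all equal).
#' @param k_target Target mode count (1 or 2).
#' @param limits Window for the KDE grid, in data units (default
#'   \code{c(0, 200)} km, the scale of foraging ranges considered here).
#' @param tol Bisection tolerance on the bandwidth.
#' @param n_grid KDE grid size.
#' @return The critical bandwidth (data units).
#' @references Silverman, B. W. (1981) Using kernel density estimates to
#'   investigate multimodality. JRSS B 43, 97-99.
#' @export
critical_bandwidth <- function(values, k_target, limits = c(0, 200),
                               tol = 1e-3, n_grid = 512) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("critical_bandwidth: need at least 3 values")
  if (stats::sd(values) == 0) {
    stop("critical_bandwidth: degenerate sample (all values identical)")
  }
  if (!(k_target %in% c(1, 2))) stop("critical_bandwidth: k_target must be 1 or 2")
  span <- diff(limits)
  hi <- span
  if (kde_modes(values, hi, limits, n_grid)$k > k_target) {
    stop("critical_bandwidth: no bracketing bandwidth found ",
         "(KDE keeps >", k_target, " modes even at bw=", hi, ")")
  }
  lo <- span / 1e5
  if (kde_modes(values, lo, limits, n_grid)$k <= k_target) {
    return(lo) # already at most k_target modes at the resolution floor
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (kde_modes(values, mid, limits, n_grid)$k <= k_target) hi <- mid else lo <- mid
  }
  hi
}

#' Locate distribution modes via the critical bandwidth
#'
#' The number of modes is tied to the dip decision: two modes if the
#' Monte-Carlo dip test rejects unimodality at \code{alpha}, otherwise
#' one. The modes are the local maxima of the Gaussian KDE evaluated at
#' the critical bandwidth for that mode count, on a 512-point grid over
#' \code{limits}.
#'
#' @param values Numeric sample of (per-individual maximum) ranges, km.
#' @param limits Mode-search window in km (default \code{c(0, 200)}).
#' @param alpha Significance level for the dip decision (default 0.05).
#' @param n_null,seed Passed to [dip_pvalue()].
#' @param tol,n_grid Passed to [critical_bandwidth()].
#' @return Object of class \code{cpf_modes}: list with \code{k},
#'   \code{modes} (ascending, km), \code{h_crit}, \code{limits},
#'   \code{dip} (the \code{cpf_dip} test result).
#' @export
mode_locations <- function(values, limits = c(0, 200), alpha = 0.05,
                           n_null = 10000, seed = 1, tol = 1e-3, n_grid = 512) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("mode_locations: need at least 3 values")
  if (stats::sd(values) == 0) {
    stop("mode_locations: degenerate sample (all values identical)")
  }
  dip <- dip_test(values, n_null = n_null, seed = seed)
  k_target <- if (dip$p_value < alpha) 2L else 1L
  h <- critical_bandwidth(values, k_target, limits = limits, tol = tol,
                          n_grid = n_grid)
  km <- kde_modes(values, h, limits, n_grid)
  structure(list(k = km$k, modes = sort(km$modes), h_crit = h,
                 limits = limits, dip = dip),
            class = "cpf_modes")
}

#' @export
print.cpf_modes <- function(x, ...) {
  cat(sprintf("Mode estimate: k = %d at h_crit = %.3f; modes at %s km (dip p = %.3g)\n",
              x$k, x$h_crit, paste(sprintf("%.1f", x$modes), collapse = ", "),
              x$dip$p_value))
  invisible(x)
}

#' One-trip-per-individual resampling check of bimodality
#'
#' Repeatedly draws a single trip per individual, recomputes the dip-test
#' p-value of the resulting maximum-range sample, and summarises the
#' p-value distribution. This guards the per-individual bimodality result
#' against unequal trip counts across individuals. The null table for the
#' dip p-values is shared across iterations (same sample size), so the
#' whole resampling run costs one null table plus one dip statistic per
#' iteration.
#'
#' @param trips Data frame with columns \code{bird_id} and
#'   \code{max_range_km} (one row per trip, one year at a time).
#' @param iterations Number of resampling iterations (default 999).
#' @param seed Integer seed (drives both the resampling and the shared
#'   null table).
#' @param alpha Significance level used for \code{prop_significant}.
#' @param n_null Monte-Carlo replicates for each dip p-value.
#' @return Object of class \code{cpf_resample}: list with
#'   \code{p_values} (length \code{iterations}), \code{prop_significant},
#'   \code{iterations}, \code{seed}.
#' @export
resample_bimodality <- function(trips, iterations = 999, seed = 1,
                                alpha = 0.05, n_null = 10000) {
  stopifnot(all(c("bird_id", "max_range_km") %in% names(trips)))
  birds <- split(trips$max_range_km, trips$bird_id)
  n_birds <- length(birds)
  if (n_birds < 3) stop("resample_bimodality: need at least 3 individuals")
  null_tab <- dip_null_table(n_birds, n_null, seed)
  p_values <- with_seed(seed + 1L, {
    vapply(seq_len(iterations), function(i) {
      samp <- vapply(birds, function(v) v[sample.int(length(v), 1L)], numeric(1))
      D <- dip_statistic(samp)
      (1 + sum(null_tab >= D)) / (n_null + 1)
    }, numeric(1))
  })
  structure(list(p_values = p_values,
                 prop_significant = mean(p_values < alpha),
                 iterations = iterations, seed = seed, alpha = alpha,
                 n_birds = n_birds),
            class = "cpf_resample")
}

#' @export
print.cpf_resample <- function(x, ...) {
  cat(sprintf("One-trip-per-individual resampling: %d iterations over %d birds; %.1f%% of p-values < %.2f\n",
              x$iterations, x$n_birds, 100 * x$prop_significant, x$alpha))
  invisible(x)
}
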