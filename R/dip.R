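#' Hartigans' dip statistic
#'
#' The dip of an empirical distribution is the smallest supremum-norm
#' distance between its ECDF and the class of unimodal distribution
#' functions. Large values indicate departure from unimodality. The
#' statistic is computed exactly: for every placement of the mode (in a
#' gap between order statistics, or at a tied value with an upward jump)
#' the minimal fit error is the larger of the two one-sided errors -- the
#' convex (greatest-convex-minorant) fit on the left and the concave
#' (least-concave-majorant) fit on the right -- subject to the monotone
#' junction of the two branches. The one-sided errors are computed by
#' incremental minorant sweeps; on the rare samples where the junction
#' constraint binds, the value is refined by bisection on the band width.
#'
#' The returned value lies in \eqn{[1/(2n), 1/4]}: the lower bound is
#' attained by samples whose ECDF is exactly fittable by a unimodal CDF
#' (e.g. equally spaced points), the upper bound in the limit by two equal
#' point masses. The statistic is invariant under strictly increasing
#' affine transforms of the data.
#'
#' @param x Numeric vector, at least 3 finite values (ties allowed).
#' @return The dip statistic (dimensionless).
#' @seealso [dip_pvalue()] for a Monte-Carlo test of unimodality.
#' @references Hartigan, J. A. and Hartigan, P. M. (1985) The dip test of
#'   unimodality. Annals of Statistics 13, 70-84.
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("dip_statistic: values must be finite")
  n <- length(x)
  if (n < 3) stop("dip_statistic: need at least 3 values")
  x <- sort(x)
  if (x[n] == x[1]) return(1 / (2 * n))
  .dip_core(x)
}

# evaluate a function with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# memoised Monte-Carlo null tables for the dip statistic
.dip_null_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the dip statistic
#'
#' Draws of the dip statistic for samples of size \code{n} from the
#' Uniform(0, 1) null. Tables are cached per (n, n_null, seed) within a
#' session, so repeated p-value computations at the same sample size (as in
#' the one-trip-per-individual resampling analysis) reuse the same null
#' draws.
#'
#' @param n Sample size under the null.
#' @param n_null Number of Monte-Carlo replicates.
#' @param seed Integer seed for the null draws.
#' @return Numeric vector of \code{n_null} dip values.
#' @export
dip_null_table <- function(n, n_null = 10000, seed = 1) {
  key <- paste(n, n_null, seed, sep = "_")
  tab <- .dip_null_cache[[key]]
  if (is.null(tab)) {
    tab <- with_seed(seed, {
      vapply(seq_len(n_null), function(i) dip_statistic(runif(n)), numeric(1))
    })
    .dip_null_cache[[key]] <- tab
  }
  tab
}

#' Monte-Carlo p-value for the dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution against the multimodal alternative. The null distribution
#' of the dip statistic is simulated from Uniform(0, 1) samples of the same
#' size (the classical least-favourable unimodal null), and the p-value is
#' \eqn{(1 + \#\{D^* \ge D\})/(n_{null} + 1)}.
#'
#' @param D Observed dip statistic from [dip_statistic()].
#' @param n Size of the observed sample.
#' @param n_null Number of Monte-Carlo null replicates (default 10000).
#' @param seed Integer seed for the null draws.
#' @return List of class \code{cpf_dip} with elements \code{D},
#'   \code{p_value}, \code{n}, \code{n_null}, \code{seed}.
#' @export
dip_pvalue <- function(D, n, n_null = 10000, seed = 1) {
  if (n < 3) stop("dip_pvalue: need n >= 3")
  if (n_null < 100) warning("dip_pvalue: fewer than 100 null replicates; p-value is coarse")
  tab <- dip_null_table(n, n_null, seed)
  p <- (1 + sum(tab >= D)) / (n_null + 1)
  structure(list(D = D, p_value = p, n = n, n_null = n_null, seed = seed),
            class = "cpf_dip")
}

#' Dip test of unimodality for a sample
#'
#' Convenience wrapper: computes the dip statistic and its Monte-Carlo
#' p-value in one call.
#'
#' @param x Numeric sample (n >= 3).
#' @inheritParams dip_pvalue
#' @return A \code{cpf_dip} list, see [dip_pvalue()].
#' @export
dip_test <- function(x, n_null = 10000, seed = 1) {
  D <- dip_statistic(x)
  dip_pvalue(D, length(x), n_null = n_null, seed = seed)
}

#' @export
print.cpf_dip <- function(x, ...) {
  cat(sprintf("Hartigans' dip test: D = %.4f, p = %.4g (n = %d, %d Monte-Carlo replicates)\n",
              x$D, x$p_value, x$n, x$n_null))
  invisible(x)
}
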