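#' Sex from the head-bill morphometric cutoff
#'
#' Classifies sex from total head-bill length when molecular sexing is
#' unavailable: female if head-bill <= 90.5 mm, male otherwise.
#'
#' @param head_bill_mm Head-bill length(s), mm (> 0).
#' @param cutoff_mm Cutoff (default 90.5 mm).
#' @return Character vector \code{"female"} / \code{"male"}.
#' @export
sex_from_headbill <- function(head_bill_mm, cutoff_mm = 90.5) {
  if (any(!is.finite(head_bill_mm)) || any(head_bill_mm <= 0)) {
    stop("sex_from_headbill: head-bill length must be positive")
  }
  ifelse(head_bill_mm <= cutoff_mm, "female", "male")
}

#' Size-corrected body condition
#'
#' Body condition is the residual of an ordinary least-squares regression
#' of capture mass on total head-bill length (a structural-size proxy),
#' pooled over all birds supplied: positive residuals indicate birds
#' heavier than expected for their size.
#'
#' @param records Data frame with \code{head_bill_mm} and
#'   \code{mass_capture_g} (>= 3 rows with both present).
#' @return Object of class \code{cpf_condition}: the input with a
#'   \code{bc} column (residual g) plus attributes \code{slope},
#'   \code{intercept}, \code{slope_ci} (95\% Wald), \code{r_squared},
#'   \code{df}.
#' @export
body_condition <- function(records) {
  ok <- is.finite(records$head_bill_mm) & is.finite(records$mass_capture_g)
  if (sum(ok) < 3) stop("body_condition: need at least 3 birds with mass and head-bill")
  if (stats::sd(records$head_bill_mm[ok]) == 0) {
    stop("body_condition: zero variance in head-bill length")
  }
  fit <- stats::lm(mass_capture_g ~ head_bill_mm, data = records[ok, ])
  records$bc <- NA_real_
  records$bc[ok] <- stats::residuals(fit)
  ci <- stats::confint(fit)["head_bill_mm", ]
  structure(records,
            slope = unname(stats::coef(fit)["head_bill_mm"]),
            intercept = unname(stats::coef(fit)[1]),
            slope_ci = unname(ci),
            r_squared = summary(fit)$r.squared,
            df = stats::df.residual(fit),
            class = c("cpf_condition", class(records)))
}

#' Relative body-mass change
#'
#' \eqn{BMC = (M_r - M_c) / M_c}: the signed proportional change between
#' capture and recapture mass. Birds without a recapture mass yield
#' \code{NA} and are excluded from the mass-change model.
#'
#' @param mass_capture_g Capture mass, g (> 0).
#' @param mass_recapture_g Recapture mass, g (may be \code{NA}).
#' @return Dimensionless proportion(s).
#' @export
relative_body_mass_change <- function(mass_capture_g, mass_recapture_g) {
  if (any(!is.finite(mass_capture_g)) || any(mass_capture_g <= 0)) {
    stop("relative_body_mass_change: capture mass must be positive")
  }
  (mass_recapture_g - mass_capture_g) / mass_capture_g
}

#' Trip-count-weighted proportion of outside-fjord trips
#'
#' Population-level proportion of outside-fjord foraging trips computed
#' from individual proportions weighted by the number of trips recorded
#' per individual (so the estimate equals the pooled trips ratio), with a
#' percentile bootstrap CI obtained by resampling individuals --
#' proportion and weight jointly -- with replacement.
#'
#' @param prop_outside Per-bird proportion of outside-fjord trips.
#' @param n_trips Per-bird trip counts (the weights).
#' @param n_boot Bootstrap iterations (default 999).
#' @param seed Integer seed.
#' @return Object of class \code{cpf_wprop}: list with \code{estimate},
#'   \code{ci_low}, \code{ci_high} (2.5/97.5 percentiles), \code{n_boot},
#'   \code{seed}.
#' @export
weighted_outside_proportion <- function(prop_outside, n_trips, n_boot = 999,
                                        seed = 1) {
  stopifnot(length(prop_outside) == length(n_trips))
  if (all(n_trips == 0)) stop("weighted_outside_proportion: all weights are zero")
  est <- sum(prop_outside * n_trips) / sum(n_trips)
  dat <- data.frame(p = prop_outside, w = n_trips)
  stat <- function(d, idx) sum(d$p[idx] * d$w[idx]) / sum(d$w[idx])
  bt <- with_seed(seed, boot::boot(dat, stat, R = n_boot))
  qs <- stats::quantile(bt$t[, 1], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(estimate = est, ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, seed = seed),
            class = "cpf_wprop")
}

#' @export
print.cpf_wprop <- function(x, ...) {
  cat(sprintf("Weighted outside-trip proportion: %.3f [%.3f, %.3f] (%d bootstrap iterations)\n",
              x$estimate, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Build the per-bird condition table
#'
#' Joins morphometrics with retained-trip counts into the per-bird table
#' feeding the condition metrics and the mass-change model: body
#' condition, relative body-mass change and outside-trip proportion per
#' bird.
#'
#' @param morpho Data frame: \code{bird_id}, \code{colony_id},
#'   \code{year}, optional \code{sex_molecular}, \code{head_bill_mm},
#'   \code{mass_capture_g}, \code{mass_recapture_g}.
#' @param trips Filtered \code{cpf_trips} table.
#' @return Data frame with added \code{sex}, \code{bc}, \code{bmc},
#'   \code{n_trips}, \code{n_outside_trips}, \code{prop_outside},
#'   \code{first_outside} (label of the first trip after capture);
#'   regression attributes as in [body_condition()].
#' @export
condition_table <- function(morpho, trips) {
  sex <- morpho$sex_molecular
  if (is.null(sex)) sex <- rep(NA_character_, nrow(morpho))
  missing_sex <- is.na(sex) | sex == ""
  sex[missing_sex] <- sex_from_headbill(morpho$head_bill_mm[missing_sex])
  morpho$sex <- sex
  df <- as.data.frame(trips)
  cnt <- if (nrow(df)) {
    agg <- stats::aggregate(cbind(n_trips = trip_index) ~ bird_id + year, df, length)
    out <- stats::aggregate(cbind(n_outside = label == "outside") ~ bird_id + year, df, sum)
    first <- df[order(df$start), ]
    first <- first[!duplicated(first[c("bird_id", "year")]), c("bird_id", "year", "label")]
    names(first)[3] <- "first_outside"
    Reduce(function(a, b) merge(a, b, by = c("bird_id", "year")), list(agg, out, first))
  } else {
    data.frame(bird_id = character(), year = integer(), n_trips = integer(),
               n_outside = integer(), first_outside = character())
  }
  m <- merge(morpho, cnt, by = c("bird_id", "year"), all.x = TRUE)
  m$prop_outside <- m$n_outside / m$n_trips
  m$bmc <- relative_body_mass_change(m$mass_capture_g, m$mass_recapture_g)
  body_condition(m)
}
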