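# Thresholds and underlying-variable scales (Stage 1 building blocks).
#
# An ordinal item with m categories is modelled as a discretized standard (or
# rescaled) normal variable y*: category i is observed when the underlying
# score falls between thresholds delta_{i-1} and delta_i (delta_0 = -Inf,
# delta_m = +Inf).  Two equivalent identifications of the scale of y* across
# K occasions are supported:
#   standard     sum_t mean_t = 0 and sum_t sd_t^2 = K
#   alternative  delta_1 = 0 and delta_2 = 1 (dichotomous: delta_1 = 0 and
#                sd_t = 1 at every occasion)

#' Thresholds from observed response proportions
#'
#' Maps category proportions of an ordinal variable to thresholds on an
#' underlying standard normal variable: threshold `i` is the standard-normal
#' quantile of the cumulative proportion of categories `1..i`.
#'
#' @param props Numeric vector. By default the `m` category proportions
#'   (summing to 1); with `cumulative = TRUE` the `m - 1` increasing cumulative
#'   proportions, each strictly inside `(0, 1)`.
#' @param cumulative Are `props` already cumulative?
#' @return Numeric vector of `m - 1` strictly increasing thresholds.
#' @examples
#' thresholds_from_props(c(0.20, 0.45, 0.35))
#' @export
thresholds_from_props <- function(props, cumulative = FALSE) {
  props <- as.numeric(props)
  if (!cumulative) {
    if (length(props) < 2L) abort("need at least two categories")
    cum <- cumsum(props)[-length(props)] / sum(props)
  } else {
    cum <- props
  }
  bad <- which(cum <= 0 | cum >= 1)
  if (length(bad)) {
    abort(sprintf(
      "cumulative proportion for category %d is %.3f; must lie strictly in (0, 1)",
      bad[1], cum[bad[1]]
    ))
  }
  if (any(diff(cum) <= 0)) {
    bad <- which(diff(cum) <= 0)[1] + 1L
    abort(sprintf("cumulative proportions are not increasing at category %d", bad))
  }
  qnorm(cum)
}

#' Underlying-variable scale
#'
#' Bundles the thresholds of an ordinal item with the per-occasion mean and
#' standard deviation of its underlying normal variable, under a named
#' identification (`"standard"` or `"alternative"`).
#'
#' @param thresholds Strictly increasing numeric vector (length `m - 1`), or a
#'   list of such vectors (one per occasion) when thresholds are
#'   occasion-specific (recalibrated items).
#' @param means,sds Numeric vectors, one entry per occasion (`sds > 0`).
#' @param parameterization `"standard"` or `"alternative"`.
#' @return An object of class `underlying_scale`.
#' @export
underlying_scale <- function(thresholds, means, sds,
                             parameterization = c("standard", "alternative")) {
  parameterization <- match.arg(parameterization)
  occ_specific <- is.list(thresholds)
  thr_list <- if (occ_specific) thresholds else list(thresholds)
  for (th in thr_list) {
    if (length(th) >= 2L && any(diff(th) <= 0)) abort("thresholds must be strictly increasing")
  }
  if (length(means) != length(sds)) abort("means and sds must have one entry per occasion")
  if (any(sds <= 0)) abort("sds must be positive")
  structure(
    list(
      thresholds = thresholds, means = as.numeric(means), sds = as.numeric(sds),
      parameterization = parameterization, occasion_specific = occ_specific
    ),
    class = "underlying_scale"
  )
}

#' @export
print.underlying_scale <- function(x, ...) {
  cat("<underlying_scale> (", x$parameterization, " parameterization)\n", sep = "")
  if (x$occasion_specific) {
    for (t in seq_along(x$thresholds)) {
      cat("  thresholds[occasion ", t, "]: ",
          paste(sprintf("%.3f", x$thresholds[[t]]), collapse = " "), "\n", sep = "")
    }
  } else {
    cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "), "\n")
  }
  cat("  means:     ", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  sds:       ", paste(sprintf("%.3f", x$sds), collapse = " "), "\n")
  invisible(x)
}

n_categories <- function(scale) {
  th <- if (scale$occasion_specific) scale$thresholds[[1]] else scale$thresholds
  length(th) + 1L
}

#' Switch between scale identifications
#'
#' Applies the affine transformation linking the standard identification
#' (means summing to zero, squared SDs summing to the number of occasions) and
#' the alternative identification (first threshold 0, second threshold 1; for
#' dichotomous items, first threshold 0 and unit SDs). Thresholds, means and
#' SDs are transformed consistently, so effect sizes are invariant and a round
#' trip is the identity.
#'
#' @param scale An [underlying_scale()].
#' @param target `"standard"` or `"alternative"`.
#' @return The rescaled `underlying_scale`.
#' @export
reparameterize <- function(scale, target = c("standard", "alternative")) {
  target <- match.arg(target)
  if (scale$occasion_specific) {
    if (target != "alternative") {
      abort("occasion-specific thresholds have no common standard rescaling")
    }
    # rescale each occasion separately: delta1 -> 0, delta2 -> 1
    th <- list(); mu <- numeric(0); sd <- numeric(0)
    for (t in seq_along(scale$thresholds)) {
      d <- scale$thresholds[[t]]
      a <- d[1]; b <- if (length(d) >= 2L) d[2] - d[1] else 1
      th[[t]] <- (d - a) / b
      mu[t] <- (scale$means[t] - a) / b
      sd[t] <- scale$sds[t] / b
    }
    return(underlying_scale(th, mu, sd, "alternative"))
  }
  if (identical(scale$parameterization, target)) return(scale)
  th <- scale$thresholds
  m <- length(th) + 1L
  K <- length(scale$means)
  if (target == "alternative") {
    if (m == 2L) {
      a <- th[1]
      b <- 1
    } else {
      a <- th[1]
      b <- th[2] - th[1]
    }
    # y' = (y - a) / b
    underlying_scale((th - a) / b, (scale$means - a) / b, scale$sds / b, "alternative")
  } else {
    # y = a + b y' with b chosen so sum sd^2 = K, a so sum mean = 0
    b <- sqrt(K / sum(scale$sds^2))
    a <- -b * mean(scale$means)
    underlying_scale(a + b * th, a + b * scale$means, b * scale$sds, "standard")
  }
}

#' Standardized change in an underlying variable
#'
#' Effect size of change between two occasions of an underlying variable:
#' `d = (mu2 - mu1) / sqrt(sd1^2 + sd2^2 - 2 rho sd1 sd2)`, the mean change in
#' units of the standard deviation of change. `|d|` of 0.2 / 0.5 / 0.8 are
#' conventionally read as small / medium / large.
#'
#' @param scale An [underlying_scale()] with two occasions (thresholds must be
#'   invariant across occasions for the comparison to be meaningful).
#' @param rho Pre-post correlation of the underlying variable.
#' @return A one-row tibble with `change`, `sd_diff`, `d` and a `magnitude`
#'   label.
#' @export
stage1_effect_size <- function(scale, rho) {
  if (scale$occasion_specific) {
    abort("thresholds differ across occasions; change is not comparable")
  }
  if (length(scale$means) != 2L) abort("effect size is defined for two occasions")
  effect_size_d(scale$means[1], scale$means[2], scale$sds[1], scale$sds[2], rho)
}

#' @rdname stage1_effect_size
#' @param mu1,mu2,sd1,sd2 Underlying-variable means and SDs at occasions 1, 2.
#' @export
effect_size_d <- function(mu1, mu2, sd1, sd2, rho) {
  sd_diff <- sqrt(sd1^2 + sd2^2 - 2 * rho * sd1 * sd2)
  if (any(!is.finite(sd_diff)) || any(sd_diff <= 0)) {
    abort("standard deviation of change is zero or undefined")
  }
  d <- (mu2 - mu1) / sd_diff
  tibble(
    change = mu2 - mu1, sd_diff = sd_diff, d = d,
    magnitude = effect_magnitude(d)
  )
}

effect_magnitude <- function(d) {
  cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE) |>
    as.character()
}

# Standardized thresholds of an underlying variable at one occasion:
# P(x <= i | occasion t) = Phi((delta_i - mu_t) / sd_t).
std_thresholds <- function(scale, occasion) {
  th <- if (scale$occasion_specific) scale$thresholds[[occasion]] else scale$thresholds
  (th - scale$means[occasion]) / scale$sds[occasion]
}
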