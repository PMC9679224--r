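# Weighted simple regression; returns slope, weighted R^2 and the weighted
# sum of squares of x (the inverse squared sensitivity of the slope).
wls_line <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  sxy <- sum(w * (x - mx) * (y - my))
  syy <- sum(w * (y - my)^2)
  b <- sxy / sxx
  r2 <- if (syy < 1e-300) 1 else (sxy^2) / (sxx * syy)
  list(slope = b, intercept = my - b * mx, r2 = r2, sxx = sxx)
}

#' Detect the exponential phase of a growth curve
#'
#' Identifies the exponential window of an absorbance time series and
#' estimates the specific growth rate as the slope of `ln(A600)` versus
#' time over that window.
#'
#' The procedure is deterministic: (1) a curve whose total absorbance range
#' is below 0.01 is flagged "no growth" (rate 0); (2) the saturating tail is
#' trimmed — when the curve rises more than `trim_ratio`-fold overall, only
#' the prefix up to the last reading below `max(A)/trim_ratio` (at least
#' `min_keep` points) is retained as the candidate exponential region;
#' (3) within the retained region every contiguous window of at least
#' `min_points` readings is fitted by weighted least squares on the log
#' scale, with weights `A^2` (the inverse-variance weights implied by
#' additive absorbance noise); (4) the window maximizing
#' `slope - z * se(slope)` is selected, where `se(slope)` uses a robust
#' global noise estimate (median absolute second difference of the
#' absorbances). The penalty suppresses short windows whose steepness is
#' within estimation noise; on noiseless data it vanishes and the rule
#' reduces to plain maximum slope. The window's weighted R-squared below
#' `r2_min` sets a low-confidence flag.
#'
#' @param times Numeric, strictly increasing (hours or days; the rate is in
#'   reciprocal input units).
#' @param a600 Absorbance readings, same length as `times`, values below
#'   1e-3 are floored before taking logs.
#' @param min_points Minimum window size (default 3).
#' @param r2_min Weighted R-squared below which the fit is flagged
#'   low-confidence (default 0.95).
#' @param z Noise penalty multiplier for window selection (default 4).
#' @param trim_ratio Fold-rise above which the saturating tail is trimmed,
#'   and the retention threshold `max(A)/trim_ratio` (default 3).
#' @param min_keep Minimum number of points retained by the trim (default 6).
#' @return An object of class `"exp_phase"`: a list with `slope` (the growth
#'   rate), `window` (index range used for the fit), `r2`, `max_a600_exp`
#'   (maximum absorbance attained during the exponential phase; for curves
#'   that do not run far beyond the logistic inflection this equals the
#'   curve maximum, which is what is reported — a monotone function of the
#'   rate when temperatures share a carrying capacity, so the OTG argmax is
#'   unaffected), `no_growth`, `low_confidence` and `sigma_a` (noise
#'   estimate).
#' @export
detect_exponential_phase <- function(times, a600, min_points = 3L,
                                     r2_min = 0.95, z = 4,
                                     trim_ratio = 3, min_keep = 6L) {
  n <- length(times)
  stopifnot(n == length(a600), n >= min_points, min_points >= 2L,
            all(diff(times) > 0))
  out <- list(slope = 0, window = c(NA_integer_, NA_integer_), r2 = NA_real_,
              max_a600_exp = max(a600), no_growth = FALSE,
              low_confidence = FALSE, sigma_a = NA_real_)
  class(out) <- "exp_phase"
  if (diff(range(a600)) < 0.01) {
    out$no_growth <- TRUE
    return(out)
  }
  af <- pmax(a600, 1e-3)
  sig <- if (n >= 4L)
    stats::median(abs(diff(af, differences = 2L))) / (sqrt(6) * 0.6745)
  else 0
  keep <- n
  if (max(af) / min(af) > trim_ratio) {
    below <- which(af <= max(af) / trim_ratio)
    keep <- if (length(below) > 0L) max(below) else min_points
    keep <- min(n, max(keep, min_keep, min_points))
  }
  tt <- times[1:keep]
  aa <- af[1:keep]
  y <- log(aa)
  best <- NULL
  best_crit <- -Inf
  best_win <- NULL
  for (i in 1:(keep - min_points + 1L)) {
    for (j in (i + min_points - 1L):keep) {
      f <- wls_line(tt[i:j], y[i:j], aa[i:j]^2)
      crit <- f$slope - z * sig / sqrt(f$sxx)
      if (crit > best_crit) {
        best_crit <- crit
        best <- f
        best_win <- c(i, j)
      }
    }
  }
  out$slope <- best$slope
  out$window <- best_win
  out$r2 <- best$r2
  out$low_confidence <- best$r2 < r2_min
  out$sigma_a <- sig
  out
}

#' @export
print.exp_phase <- function(x, ...) {
  if (x$no_growth) {
    cat("Exponential phase: no growth (absorbance range < 0.01)\n")
  } else {
    cat(sprintf(
      "Exponential phase: points %d-%d, rate %.4f (R2 %.3f%s), max A600 %.3f\n",
      x$window[1], x$window[2], x$slope, x$r2,
      if (x$low_confidence) ", low confidence" else "", x$max_a600_exp))
  }
  invisible(x)
}

#' Estimate growth parameters per strain
#'
#' Fits every replicate curve with [detect_exponential_phase()] and
#' summarizes, per (strain, temperature), the mean and standard deviation of
#' the growth rate Gr and the mean maximum absorbance within the exponential
#' region. The optimal temperature for growth (OTG) of a strain is the
#' temperature with the highest mean exponential-phase maximum A600; exact
#' ties are broken toward the lower temperature (with a message).
#'
#' @param curves `data.frame` with columns `strain`, `temperature`,
#'   `replicate`, `time`, `a600`.
#' @param ... Passed to [detect_exponential_phase()].
#' @return An object of class `"growth_params"`: list with `by_temp`
#'   (`data.frame`: strain, temperature, gr_mean, gr_sd, max_a600_exp,
#'   n_replicates, n_no_growth) and `otg` (`data.frame`: strain, otg).
#' @export
estimate_growth_params <- function(curves, ...) {
  need <- c("strain", "temperature", "replicate", "time", "a600")
  stopifnot(all(need %in% names(curves)))
  per_rep <- list()
  for (key in split(seq_len(nrow(curves)),
                    interaction(curves$strain, curves$temperature,
                                curves$replicate, drop = TRUE))) {
    d <- curves[key, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    ph <- detect_exponential_phase(d$time, d$a600, ...)
    per_rep[[length(per_rep) + 1L]] <- data.frame(
      strain = d$strain[1], temperature = d$temperature[1],
      replicate = d$replicate[1], gr = ph$slope,
      max_a600_exp = ph$max_a600_exp, no_growth = ph$no_growth,
      stringsAsFactors = FALSE
    )
  }
  per_rep <- do.call(rbind, per_rep)

  agg <- do.call(rbind, lapply(
    split(per_rep, interaction(per_rep$strain, per_rep$temperature,
                               drop = TRUE)),
    function(d) data.frame(
      strain = d$strain[1], temperature = d$temperature[1],
      gr_mean = mean(d$gr),
      gr_sd = if (nrow(d) >= 2L) stats::sd(d$gr) else NA_real_,
      max_a600_exp = mean(d$max_a600_exp),
      n_replicates = nrow(d), n_no_growth = sum(d$no_growth),
      stringsAsFactors = FALSE
    )))
  agg <- agg[order(agg$strain, agg$temperature), , drop = FALSE]
  rownames(agg) <- NULL

  otg <- do.call(rbind, lapply(split(agg, agg$strain), function(d) {
    top <- d$temperature[d$max_a600_exp == max(d$max_a600_exp)]
    if (length(top) > 1L)
      message("OTG tie for ", d$strain[1], "; lower temperature chosen")
    data.frame(strain = d$strain[1], otg = min(top), stringsAsFactors = FALSE)
  }))
  rownames(otg) <- NULL

  out <- list(by_temp = agg, otg = otg, replicates = per_rep)
  class(out) <- "growth_params"
  out
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth parameters (Gr = exponential-phase log-slope per input time unit)\n")
  for (s in unique(x$by_temp$strain)) {
    d <- x$by_temp[x$by_temp$strain == s, , drop = FALSE]
    cat(sprintf("  %s (OTG %g):\n", s, x$otg$otg[x$otg$strain == s]))
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %5g: Gr %.4f +/- %s  max A600(exp) %.3f%s\n",
                  d$temperature[i], d$gr_mean[i],
                  ifelse(is.na(d$gr_sd[i]), "NA", sprintf("%.4f", d$gr_sd[i])),
                  d$max_a600_exp[i],
                  if (d$n_no_growth[i] == d$n_replicates[i]) "  [no growth]"
                  else ""))
  }
  invisible(x)
}

#' @export
summary.growth_params <- function(object, ...) {
  merge(object$otg, stats::aggregate(gr_mean ~ strain, object$by_temp, max),
        by = "strain")
}

#' @export
coef.growth_params <- function(object, ...) {
  stats::setNames(object$otg$otg, object$otg$strain)
}

#' Read growth curves from TSV
#'
#' @param path Tab-separated file with header columns `strain`,
#'   `temperature`, `replicate`, `time`, `a600`.
#' @return A `data.frame` suitable for [estimate_growth_params()].
#' @export
read_growth_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "temperature", "replicate", "time", "a600")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L)
    stop("growth TSV lacks column(s): ", paste(missing, collapse = ", "))
  d
}
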