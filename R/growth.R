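#' Construct a growth curve
#'
#' One well's OD600 time series with its strain, medium, replicate, and
#' well provenance. Times are hours and must be strictly increasing; at
#' least 7 time points are required so that a window of 5 consecutive
#' interval rates exists.
#'
#' @param strain strain (gene) id.
#' @param medium medium label.
#' @param replicate replicate index.
#' @param plate,well plate id and well id (e.g. `"A1"`).
#' @param times numeric vector of hours, strictly increasing.
#' @param od OD600 readings, same length as `times`.
#' @param blank OD600 blank offset subtracted before rate computation.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(strain, medium, replicate, plate = NA, well = NA,
                         times, od, blank = 0) {
  if (length(times) < 7L)
    stop("growth curve needs >= 7 time points (>= 6 intervals)")
  if (length(od) != length(times)) stop("od and times lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(od))) stop("od must be finite")
  structure(list(strain = strain, medium = medium, replicate = replicate,
                 plate = plate, well = well, times = as.numeric(times),
                 od = as.numeric(od), blank = blank),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s (%s, rep %s) %d points, %.1f-%.1f h\n",
              x$strain, x$medium, as.character(x$replicate),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Per-interval exponential growth rates
#'
#' For each consecutive pair of readings the rate is
#' `mu_i = ln(C_{i+1}/C_i) / (t_{i+1} - t_i)` on blank-corrected OD values.
#' Intervals where either endpoint sits below the positivity floor
#' (`blank + floor` on the raw scale, i.e. corrected OD < `floor`) are
#' masked: their rate is `NA` and `valid` is `FALSE`, since the log of
#' reader noise carries no growth information.
#'
#' @param curve a [growth_curve()].
#' @param floor positivity floor on blank-corrected OD (default 0.003).
#' @return data.frame with `t_mid` (interval midpoint, h), `mu` (h^-1),
#'   `valid`; one row per consecutive pair.
#' @export
interval_rates <- function(curve, floor = 0.003) {
  od <- curve$od - curve$blank
  n <- length(od)
  if (n < 2L) stop("fewer than 2 readings: no interval rates")
  ok <- od[-n] >= floor & od[-1] >= floor
  mu <- rep(NA_real_, n - 1L)
  mu[ok] <- log(od[-1][ok] / od[-n][ok]) / diff(curve$times)[ok]
  data.frame(t_mid = (curve$times[-n] + curve$times[-1]) / 2,
             mu = mu, valid = ok)
}

# Window statistics over all runs of `window` consecutive valid rates.
# Returns a data.frame(start, mean, sd) or NULL when no window exists.
window_stats <- function(mu, valid, window = 5L) {
  n <- length(mu)
  if (n < window) return(NULL)
  starts <- which(vapply(seq_len(n - window + 1L), function(s)
    all(valid[s:(s + window - 1L)]), logical(1)))
  if (!length(starts)) return(NULL)
  data.frame(start = starts,
             mean = vapply(starts, function(s)
               mean(mu[s:(s + window - 1L)]), numeric(1)),
             sd = vapply(starts, function(s)
               stats::sd(mu[s:(s + window - 1L)]), numeric(1)))
}

#' Estimate the exponential growth rate of one curve
#'
#' Computes all interval rates, scans every window of `window` consecutive
#' valid rates, and selects the window by: maximal window mean; among
#' windows whose mean is within 5% of that maximum, minimal standard
#' deviation; remaining ties broken by the earliest window. The estimate is
#' the mean of the selected window's rates. A curve with no valid window,
#' or whose best window mean is not positive, is flagged `no_growth`
#' (matching the practice of re-scoring wells that show no growth). The
#' curve's growth maximum `max_od` is the largest blank-corrected reading,
#' taken without smoothing.
#'
#' @param curve a [growth_curve()].
#' @param window number of consecutive interval rates averaged (default 5).
#' @param floor positivity floor passed to [interval_rates()].
#' @return one-row data.frame: `strain`, `medium`, `replicate`, `plate`,
#'   `well`, `mu`, `window_start_index`, `window_sd`, `max_od`,
#'   `no_growth`.
#' @export
estimate_growth_rate <- function(curve, window = 5L, floor = 0.003) {
  ir <- interval_rates(curve, floor = floor)
  ws <- window_stats(ir$mu, ir$valid, window)
  res <- data.frame(strain = curve$strain, medium = curve$medium,
                    replicate = curve$replicate, plate = curve$plate,
                    well = curve$well, mu = NA_real_,
                    window_start_index = NA_integer_, window_sd = NA_real_,
                    max_od = max(curve$od - curve$blank),
                    no_growth = TRUE, stringsAsFactors = FALSE)
  if (is.null(ws)) return(res)
  best_mean <- max(ws$mean)
  if (best_mean <= 0) return(res)
  cand <- ws[ws$mean >= 0.95 * best_mean, , drop = FALSE]
  cand <- cand[order(cand$sd, cand$start), , drop = FALSE]
  res$mu <- cand$mean[1]
  res$window_start_index <- cand$start[1]
  res$window_sd <- cand$sd[1]
  res$no_growth <- FALSE
  res
}

#' Estimate growth rates for a set of curves
#'
#' @param curves list of [growth_curve()] objects.
#' @param window,floor passed to [estimate_growth_rate()].
#' @return data.frame of per-curve estimates (one row per curve).
#' @export
estimate_growth_rates <- function(curves, window = 5L, floor = 0.003) {
  out <- do.call(rbind, lapply(curves, estimate_growth_rate,
                               window = window, floor = floor))
  rownames(out) <- NULL
  out
}

#' Aggregate replicate growth-rate estimates per strain and medium
#'
#' Means and standard errors (sd/sqrt(n)) over the replicates that grew;
#' no-growth replicates are excluded and counted. Strains whose replicates
#' all failed to grow are dropped from the table and listed in the
#' `no_growth_strains` attribute. A single-replicate strain gets SE 0 and
#' `degenerate_n = TRUE`.
#'
#' @param estimates data.frame from [estimate_growth_rates()].
#' @return data.frame (class `rate_table`) with `strain`, `medium`,
#'   `mean_mu`, `se_mu`, `n`, `mean_max_od`, `degenerate_n`.
#' @export
aggregate_replicates <- function(estimates) {
  if (!nrow(estimates)) stop("empty estimate table")
  grown <- estimates[!estimates$no_growth, , drop = FALSE]
  key_all <- unique(estimates[c("strain", "medium")])
  key <- unique(grown[c("strain", "medium")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    g <- grown[grown$strain == key$strain[i] & grown$medium == key$medium[i], ]
    n <- nrow(g)
    data.frame(strain = key$strain[i], medium = key$medium[i],
               mean_mu = mean(g$mu),
               se_mu = if (n > 1) stats::sd(g$mu) / sqrt(n) else 0,
               n = n, mean_max_od = mean(g$max_od),
               degenerate_n = n == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- key_all[!paste(key_all$strain, key_all$medium) %in%
                       paste(key$strain, key$medium), , drop = FALSE]
  attr(out, "no_growth_strains") <- dropped
  attr(out, "n_no_growth_replicates") <- sum(estimates$no_growth)
  class(out) <- c("rate_table", class(out))
  out
}

#' Well-location bias diagnostic
#'
#' Averages the growth rate and growth maximum of all strains measured in
#' each well (across plates) and correlates both against the serpentine
#' well index. A carrying-capacity bias shows up as a strong monotone trend
#' in the per-well mean maximal OD while the per-well mean rates stay
#' trendless.
#'
#' @param estimates data.frame from [estimate_growth_rates()] with `well`
#'   filled in.
#' @return list with `per_well` (data.frame `well`, `index`, `n`,
#'   `mean_mu`, `mean_max_od`) and `trend` (data.frame of Spearman rho and
#'   p for `mu` and `max_od` against the well index).
#' @export
well_bias_diagnostic <- function(estimates) {
  grown <- estimates[!estimates$no_growth, , drop = FALSE]
  if (!nrow(grown)) stop("no grown estimates")
  wells <- sort(unique(grown$well))
  if (length(wells) < 2L) stop("well trend undefined for a single well")
  per_well <- do.call(rbind, lapply(wells, function(w) {
    g <- grown[grown$well == w, ]
    data.frame(well = w, index = serpentine_index(w), n = nrow(g),
               mean_mu = mean(g$mu), mean_max_od = mean(g$max_od),
               stringsAsFactors = FALSE)
  }))
  if (min(per_well$n) < 2L)
    warning("some wells hold a single strain; per-well means are noisy")
  tr_mu <- spearman_cor(per_well$index, per_well$mean_mu)
  tr_od <- spearman_cor(per_well$index, per_well$mean_max_od)
  trend <- data.frame(quantity = c("mu", "max_od"),
                      rho = c(tr_mu$rho, tr_od$rho),
                      p = c(tr_mu$p, tr_od$p))
  list(per_well = per_well, trend = trend)
}

#' Correlation between growth rate and growth maximum across strains
#'
#' @param rate_table a [aggregate_replicates()] table.
#' @param medium medium label to subset on.
#' @return list with `rho` and `p` (Spearman).
#' @export
rate_vs_max_correlation <- function(rate_table, medium) {
  rt <- rate_table[rate_table$medium == medium, , drop = FALSE]
  if (nrow(rt) < 3L) stop("need >= 3 strains")
  spearman_cor(rt$mean_mu, rt$mean_max_od)
}
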