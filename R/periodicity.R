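#' Circular sliding-window mean of a per-anchor series
#'
#' Left-anchored smoother: the value at anchor `a` is the mean of the
#' `width` consecutive bins `[a, a + width)`, wrapping around the circular
#' genome.
#'
#' @param values numeric vector, one value per anchor.
#' @param width window width in bins.
#' @return numeric vector of the same length.
#' @export
smooth_circular <- function(values, width) {
  n <- length(values)
  width <- as.integer(width)
  if (width < 1L || width > n) stop("window width outside [1, length]")
  cs <- c(0, cumsum(c(values, values[seq_len(width)])))
  (cs[seq_len(n) + width] - cs[seq_len(n)]) / width
}

#' Positional signal: sliding-window means of per-gene values on the genome
#'
#' Builds the 1-kb-anchored circular series used for genomic profiles and
#' periodicity analysis: at each anchor `a` the value is the mean of the
#' supplied per-gene values over genes whose midpoint lies in the circular
#' window `[a, a + window)` kb. Three modes control the gene set:
#' `essential_zero` includes every gene but forces essential genes to value
#' 0 (a deleted essential gene means no growth), `nonessential_only` drops
#' essential genes, and `density` ignores `values` and counts the genes per
#' window (used for, e.g., essential-gene density when passed an
#' essential-only annotation). Windows containing no gene are filled with
#' the global mean of the non-empty windows, which is neutral once the
#' series is mean-centred for the Fourier transform.
#'
#' @param annotation annotation data.frame with `gene`, `midpoint_kb`, and
#'   `essential` (0/1).
#' @param values numeric vector of per-gene values, named by gene id or
#'   aligned with the annotation rows. Ignored in `density` mode.
#' @param genome_length_kb circular genome length, kb.
#' @param mode `"essential_zero"`, `"nonessential_only"`, or `"density"`.
#' @param bin_step anchor spacing, kb (default 1).
#' @param window sliding window width, kb (default 100).
#' @return object of class `positional_signal`: list with `values`,
#'   `n_contributing`, `filled`, `anchors_kb`, `bin_step`, `window`,
#'   `genome_length`, `mode`.
#' @export
positional_signal <- function(annotation, values = NULL, genome_length_kb,
                              mode = c("essential_zero", "nonessential_only",
                                       "density"),
                              bin_step = 1, window = 100) {
  mode <- match.arg(mode)
  if (!nrow(annotation)) stop("empty annotation")
  n_bins <- genome_length_kb / bin_step
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("genome_length_kb must be a multiple of bin_step")
  n_bins <- as.integer(round(n_bins))
  w_bins <- window / bin_step
  if (abs(w_bins - round(w_bins)) > 1e-9)
    stop("window must be a multiple of bin_step")
  w_bins <- as.integer(round(w_bins))

  ann <- annotation
  if (mode == "nonessential_only") ann <- ann[ann$essential == 0L, , drop = FALSE]
  if (!nrow(ann)) stop("no genes left after mode filtering")
  if (mode == "density") {
    v <- rep(0, nrow(ann))
  } else {
    if (is.null(values)) stop("values required outside density mode")
    v <- if (!is.null(names(values))) {
      if (!all(ann$gene %in% names(values)))
        stop("values missing for some genes")
      unname(values[ann$gene])
    } else {
      if (length(values) != nrow(annotation))
        stop("unnamed values must align with the annotation rows")
      values[annotation$gene %in% ann$gene]
    }
    if (mode == "essential_zero") v[ann$essential == 1L] <- 0
    if (!all(is.finite(v))) stop("non-finite per-gene values")
  }
  mid <- ann$midpoint_kb %% genome_length_kb
  bin <- as.integer(floor(mid / bin_step)) %% n_bins
  bin_sum <- rep(0, n_bins)
  tab <- tapply(v, bin, sum)
  bin_sum[as.integer(names(tab)) + 1L] <- as.numeric(tab)
  bin_cnt <- tabulate(bin + 1L, nbins = n_bins)

  win_sum <- smooth_circular(bin_sum, w_bins) * w_bins
  win_cnt <- round(smooth_circular(bin_cnt, w_bins) * w_bins)
  if (mode == "density") {
    vals <- win_cnt
    filled <- rep(FALSE, n_bins)
  } else {
    vals <- ifelse(win_cnt > 0, win_sum / pmax(win_cnt, 1L), NA_real_)
    filled <- win_cnt == 0L
    if (all(filled)) stop("every window is empty")
    vals[filled] <- mean(vals[!filled])
  }
  structure(list(values = vals, n_contributing = win_cnt, filled = filled,
                 anchors_kb = (seq_len(n_bins) - 1L) * bin_step,
                 bin_step = bin_step, window = window,
                 genome_length = genome_length_kb, mode = mode),
            class = "positional_signal")
}

#' Positional signal from a complete per-anchor series
#'
#' Wraps an already per-anchor numeric series (e.g. a constructed harmonic)
#' in the same container and, by default, applies the same 100-kb circular
#' sliding-window mean that [positional_signal()] applies to per-gene data,
#' so constructed series follow the identical smoothing path.
#'
#' @param values numeric per-anchor series covering the whole circle.
#' @param bin_step anchor spacing, kb.
#' @param window smoothing window, kb; use `smooth = FALSE` to skip.
#' @param smooth apply the circular window mean (default TRUE).
#' @return a `positional_signal`.
#' @export
positional_signal_from_series <- function(values, bin_step = 1, window = 100,
                                          smooth = TRUE) {
  n <- length(values)
  L <- n * bin_step
  v <- if (smooth) smooth_circular(values, window / bin_step) else values
  structure(list(values = v, n_contributing = rep(NA_integer_, n),
                 filled = rep(FALSE, n),
                 anchors_kb = (seq_len(n) - 1L) * bin_step,
                 bin_step = bin_step, window = if (smooth) window else 0,
                 genome_length = L, mode = "series"),
            class = "positional_signal")
}

#' @export
print.positional_signal <- function(x, ...) {
  cat(sprintf("<positional_signal> %d anchors over %g kb (window %g kb, mode %s)\n",
              length(x$values), x$genome_length, x$window, x$mode))
  invisible(x)
}

signal_values <- function(signal) {
  if (inherits(signal, "positional_signal")) signal$values
  else as.numeric(signal)
}

#' Fourier periodogram of a circular positional signal
#'
#' Mean-subtracts the series and takes the discrete Fourier transform;
#' the spectral power at harmonic k (k = 1..floor(N/2)) is the squared
#' modulus of the k-th coefficient divided by N, and the wavelength of
#' harmonic k is `genome_length / k`. The scaling satisfies Parseval's
#' identity: twice the summed half-spectrum power, minus the Nyquist power
#' when N is even, equals the sum of squares of the detrended series.
#'
#' @param signal a `positional_signal` or plain numeric series.
#' @param genome_length_kb genome length; taken from the signal when
#'   omitted.
#' @return object of class `periodogram_result`: list with `k`,
#'   `wavelength`, `power`, `n`, `genome_length`, `constant` flag.
#' @export
periodogram <- function(signal, genome_length_kb = NULL) {
  v <- signal_values(signal)
  L <- genome_length_kb %||%
    (if (inherits(signal, "positional_signal")) signal$genome_length
     else length(v))
  N <- length(v)
  if (N < 4L) stop("series too short for a periodogram")
  x <- v - mean(v)
  ft <- stats::fft(x)
  k <- seq_len(N %/% 2L)
  power <- Mod(ft[k + 1L])^2 / N
  structure(list(k = k, wavelength = L / k, power = power, n = N,
                 genome_length = L, coef = ft[k + 1L],
                 constant = sum(power) <= 0),
            class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  if (x$constant) {
    cat("<periodogram_result> constant series: zero spectrum\n")
  } else {
    kd <- x$k[which.max(x$power)]
    cat(sprintf("<periodogram_result> %d ordinates; peak k = %d (wavelength %.1f kb)\n",
                length(x$k), kd, x$genome_length / kd))
  }
  invisible(x)
}

#' Fisher's g test for a hidden periodicity
#'
#' g is the largest periodogram ordinate divided by the sum of ordinates;
#' the exact null tail probability is
#' `p = sum_{j=1..floor(1/g)} (-1)^(j-1) C(n, j) (1 - j g)^(n-1)` with n
#' the number of ordinates, clipped to [0, 1]. Terms are accumulated in log
#' magnitude and the series is truncated once the remaining terms are
#' negligible.
#'
#' @param powers numeric vector of periodogram ordinates, or a
#'   `periodogram_result`.
#' @return list with `g`, `p`, and `n` (ordinates used).
#' @export
fisher_g_test <- function(powers) {
  if (inherits(powers, "periodogram_result")) powers <- powers$power
  powers <- as.numeric(powers)
  if (length(powers) < 2L) stop("need >= 2 periodogram ordinates")
  if (any(powers < 0)) stop("negative spectral power")
  tot <- sum(powers)
  if (tot <= 0) stop("all-zero spectrum: g undefined")
  g <- max(powers) / tot
  list(g = g, p = fisher_g_pvalue(g, length(powers)), n = length(powers))
}

fisher_g_pvalue <- function(g, n) {
  if (g >= 1) return(0)
  if (g <= 0) return(1)
  jmax <- floor(1 / g)
  s <- 0
  for (j in seq_len(jmax)) {
    lt <- lchoose(n, j) + (n - 1) * log1p(-j * g)
    term <- exp(lt)
    if (!is.finite(term)) { s <- 1; break }   # saturated: p is 1
    s <- s + if (j %% 2L == 1L) term else -term
    if (s >= 1) { s <- 1; break }
    if (term < 1e-16 * max(abs(s), 1e-300) && j > 1L) break
  }
  min(max(s, 0), 1)
}

#' Least-squares sinusoid fit at harmonic k
#'
#' Fits `m + A cos(2 pi k x / L + phi)` to the series by least squares.
#' Because the harmonics are orthogonal on the circular grid the solution
#' is closed-form from the k-th Fourier coefficient: `A = 2 |c_k| / N`,
#' `phi = Arg(c_k)`, `m` the series mean.
#'
#' @param signal a `positional_signal` or numeric series.
#' @param k harmonic index (cycles per genome), >= 1.
#' @return list with `amplitude`, `phase`, `offset`, `k`, `fitted` (the
#'   fitted series), and `rss`.
#' @export
fit_sinusoid <- function(signal, k) {
  v <- signal_values(signal)
  N <- length(v)
  if (k < 1L || k > N %/% 2L) stop("k outside [1, N/2]")
  x <- v - mean(v)
  ck <- sum(x * exp(-2i * pi * k * (seq_len(N) - 1L) / N))
  A <- 2 * Mod(ck) / N
  phi <- Arg(ck)
  fitted <- mean(v) + A * cos(2 * pi * k * (seq_len(N) - 1L) / N + phi)
  list(amplitude = A, phase = phi, offset = mean(v), k = as.integer(k),
       fitted = fitted, rss = sum((v - fitted)^2))
}

#' Dominant chromosomal period of a positional signal
#'
#' Finds the harmonic of maximal spectral power — by default excluding the
#' k = 1 full-genome-length harmonic, which reflects the genome itself
#' rather than a periodicity within it — then reports its wavelength, the
#' least-squares sinusoid at that harmonic, and Fisher's g with its exact
#' p-value computed over the ordinates considered (k >= 2 when k = 1 is
#' excluded). Power ties resolve to the smaller k.
#'
#' @param signal a `positional_signal` or numeric series.
#' @param exclude_k1 drop the full-genome harmonic before taking the
#'   maximum (default TRUE).
#' @return list with `k`, `wavelength` (kb), `n_periods`, `power`,
#'   `fit` (from [fit_sinusoid()]), `g`, `p`, `k1_excluded`.
#' @export
dominant_period <- function(signal, exclude_k1 = TRUE) {
  pg <- periodogram(signal)
  if (pg$constant) stop("flat spectrum: dominant period undefined")
  keep <- if (exclude_k1) pg$k >= 2L else rep(TRUE, length(pg$k))
  kk <- pg$k[keep]; pw <- pg$power[keep]
  if (sum(pw) <= 0) stop("flat spectrum after excluding k = 1")
  k_dom <- kk[which.max(pw)]          # which.max takes the first = smallest k
  gt <- fisher_g_test(pw)
  list(k = as.integer(k_dom), wavelength = pg$genome_length / k_dom,
       n_periods = as.integer(k_dom), power = max(pw),
       fit = fit_sinusoid(signal, k_dom), g = gt$g, p = gt$p,
       k1_excluded = exclude_k1)
}

#' Correlation between two positional signals
#'
#' Pearson correlation across the 1-kb anchors of two signals on the same
#' grid — used to compare the genomic profile of knockout growth rates with
#' the essential-gene density profile.
#'
#' @param signal_a,signal_b `positional_signal`s or numeric series of equal
#'   length.
#' @return list with `r` (Pearson) and `p`.
#' @export
essential_density_correlation <- function(signal_a, signal_b) {
  a <- signal_values(signal_a); b <- signal_values(signal_b)
  if (length(a) != length(b)) stop("signals differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant signal")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
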