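# Shared fixtures, built in code.

# Noise-free exponential growth curve C0 * exp(mu * t).
exp_curve <- function(mu, times = seq(0, 6, by = 0.25), od0 = 0.01,
                      blank = 0, strain = "s1", medium = "LB",
                      replicate = 1, well = "A1") {
  growth_curve(strain = strain, medium = medium, replicate = replicate,
               well = well, times = times, od = blank + od0 * exp(mu * times),
               blank = blank)
}

# Noise-free logistic curve with carrying capacity K.
logistic_curve <- function(mu, K = 1, od0 = 0.01,
                           times = seq(0, 24, by = 0.5), blank = 0,
                           strain = "s1", medium = "LB", replicate = 1,
                           well = "A1") {
  od <- K / (1 + ((K - od0) / od0) * exp(-mu * times))
  growth_curve(strain = strain, medium = medium, replicate = replicate,
               well = well, times = times, od = blank + od, blank = blank)
}

# Exhaustive-search oracle for the 5-window selection rule: maximal mean,
# then minimal sd among windows within 5% of it, then earliest start.
brute_force_window <- function(mu, valid, window = 5L) {
  n <- length(mu)
  best <- NULL
  cand <- list()
  for (s in seq_len(max(n - window + 1L, 0L))) {
    idx <- s:(s + window - 1L)
    if (!all(valid[idx])) next
    cand[[length(cand) + 1L]] <- list(start = s, mean = mean(mu[idx]),
                                      sd = sd(mu[idx]))
  }
  if (!length(cand)) return(NULL)
  means <- vapply(cand, `[[`, 0, "mean")
  top <- max(means)
  keep <- cand[means >= 0.95 * top]
  sds <- vapply(keep, `[[`, 0, "sd")
  starts <- vapply(keep, `[[`, 0, "start")
  ord <- order(sds, starts)
  keep[[ord[1]]]
}

# Small rate table built directly from per-strain means.
rate_table_from <- function(mu, medium = "LB",
                            strains = sprintf("s%03d", seq_along(mu)),
                            max_od = rep(1, length(mu))) {
  structure(data.frame(strain = strains, medium = medium, mean_mu = mu,
                       se_mu = 0, n = 3L, mean_max_od = max_od,
                       degenerate_n = FALSE, stringsAsFactors = FALSE),
            class = c("rate_table", "data.frame"))
}

# Minimal annotation with explicit midpoints (1-kb genes centred there).
annotation_at <- function(midpoints_kb, genome_length_kb,
                          essential = rep(0L, length(midpoints_kb)),
                          category = rep("e", length(midpoints_kb))) {
  start <- round(midpoints_kb * 1000)
  data.frame(gene = sprintf("g%03d", seq_along(midpoints_kb)),
             start_bp = start + 1, end_bp = start + 1, strand = "+",
             essential = essential, category = category,
             midpoint_kb = midpoints_kb, stringsAsFactors = FALSE)
}
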