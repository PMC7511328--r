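#' Configuration for the synthetic knockout-fitness dataset generator
#'
#' Builds and validates the parameter set for the synthetic-data module. The
#' generator emulates the three inputs of the pipeline: a circular-genome
#' gene annotation, per-gene wild-type expression tables (log10 RPKM,
#' replicated), and plate-reader OD600 growth curves for the single-gene
#' knockout strains. Defaults describe an E. coli-like study: a 4,632-kb
#' circular genome, ~4,200 genes of which ~7% are essential, a six-period
#' sinusoidal positional component shared (with reversed sign) by expression
#' and knockout growth, and a target Spearman correlation of -0.37 between
#' wild-type expression and knockout growth rate.
#'
#' @param genome_length_kb circular genome length in kb.
#' @param n_genes number of genes to place.
#' @param essential_fraction proportion of genes flagged essential, in [0, 1).
#' @param category_labels named numeric vector of functional-category
#'   sampling weights (short codes as names).
#' @param n_periods number of positional harmonic cycles over the genome.
#' @param positional_amplitude_expr amplitude of the expression positional
#'   cosine, log10-RPKM units.
#' @param positional_amplitude_growth amplitude of the growth positional
#'   cosine, h^-1; enters the knockout growth truth with reversed sign.
#' @param positional_phase phase of the positional cosine, radians.
#' @param target_rho target Spearman correlation between per-gene mean
#'   expression and true knockout growth rate, in [-1, 0].
#' @param media named list; each element a list with `mu` (wild-type
#'   exponential rate, h^-1) and `K` (carrying capacity, OD600).
#' @param n_replicates biological replicates per strain and medium.
#' @param well_bias_slope carrying-capacity bias per serpentine well index,
#'   OD600 units (bias acts on K only, never on the rate).
#' @param baseline_expr baseline log10 RPKM.
#' @param gene_effect_sd sd of the gene-specific expression effect.
#' @param expression_sd replicate noise sd of expression, log10 RPKM.
#' @param growth_residual_sd sd of the gene-level residual on true knockout
#'   growth rate, h^-1.
#' @param growth_replicate_sd replicate-to-replicate sd of the realized
#'   growth rate, h^-1 (not stated by typical study designs; exposed as a
#'   free parameter).
#' @param od_sd additive measurement noise sd on OD600 readings.
#' @param od0 inoculum OD600.
#' @param blank plate blank OD600 offset; readings are truncated below at
#'   this floor.
#' @param interval_h plate-reader sampling interval, hours.
#' @param duration_h assay duration, hours.
#' @param seed integer master seed; all generator stages derive their own
#'   substreams from it.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(genome_length_kb = 4632,
                             n_genes = 4200L,
                             essential_fraction = 0.072,
                             category_labels = c(
                               e = 0.22, t = 0.10, f = 0.05, s = 0.04,
                               cp = 0.06, r = 0.04, c = 0.03, l = 0.03,
                               m = 0.04, d = 0.03, o = 0.10, pe = 0.07,
                               pm = 0.05, pr = 0.07, pt = 0.07),
                             n_periods = 6L,
                             positional_amplitude_expr = 0.15,
                             positional_amplitude_growth = 0.02,
                             positional_phase = 0,
                             target_rho = -0.37,
                             media = list(
                               LB  = list(mu = 1.2,  K = 1.0),
                               M63 = list(mu = 0.45, K = 0.5)),
                             n_replicates = 3L,
                             well_bias_slope = 0.002,
                             baseline_expr = 2.0,
                             gene_effect_sd = 0.6,
                             expression_sd = 0.2,
                             growth_residual_sd = 0.05,
                             growth_replicate_sd = 0.02,
                             od_sd = 0.003,
                             od0 = 0.01,
                             blank = 0.08,
                             interval_h = 0.5,
                             duration_h = 24,
                             seed = 1L) {
  cfg <- list(genome_length_kb = genome_length_kb, n_genes = as.integer(n_genes),
              essential_fraction = essential_fraction,
              category_labels = category_labels,
              n_periods = as.integer(n_periods),
              positional_amplitude_expr = positional_amplitude_expr,
              positional_amplitude_growth = positional_amplitude_growth,
              positional_phase = positional_phase,
              target_rho = target_rho, media = media,
              n_replicates = as.integer(n_replicates),
              well_bias_slope = well_bias_slope,
              baseline_expr = baseline_expr, gene_effect_sd = gene_effect_sd,
              expression_sd = expression_sd,
              growth_residual_sd = growth_residual_sd,
              growth_replicate_sd = growth_replicate_sd,
              od_sd = od_sd, od0 = od0, blank = blank,
              interval_h = interval_h, duration_h = duration_h,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$genome_length_kb > 0,
            cfg$n_genes >= 1L,
            cfg$essential_fraction >= 0, cfg$essential_fraction < 1,
            cfg$n_periods >= 0L,
            cfg$target_rho >= -1, cfg$target_rho <= 0,
            cfg$n_replicates >= 1L,
            cfg$expression_sd >= 0, cfg$gene_effect_sd >= 0,
            cfg$growth_residual_sd >= 0, cfg$growth_replicate_sd >= 0,
            cfg$od_sd >= 0, cfg$od0 > 0, cfg$blank >= 0,
            cfg$interval_h > 0, cfg$duration_h > cfg$interval_h)
  if (is.null(names(cfg$category_labels)) || any(cfg$category_labels <= 0))
    stop("category_labels must be a named vector of positive weights")
  for (m in cfg$media)
    stopifnot(m$mu > 0, m$K > cfg$od0)
  invisible(cfg)
}

#' Generate a circular-genome gene annotation
#'
#' Places `n_genes` genes with uniformly scattered midpoints on the circular
#' genome, draws gene lengths from a gamma distribution clipped to a
#' realistic bacterial range, flags essential genes at the configured
#' fraction, and samples flat functional-category codes by weight.
#' Coordinates are 1-based inclusive base pairs; genes may wrap across the
#' origin. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `gene`, `start_bp`, `end_bp`, `strand`,
#'   `essential` (0/1), `category`, `midpoint_kb`.
#' @export
generate_annotation <- function(config) {
  validate_synthetic_config(config)
  L_bp <- round(config$genome_length_kb * 1000)
  min_len <- 90L
  if (config$n_genes * min_len > L_bp)
    stop("placement failure: ", config$n_genes, " genes of >= ", min_len,
         " bp cannot be placed on a ", L_bp, " bp genome")
  with_local_seed(derive_seed(config$seed, "annotation"), {
    n <- config$n_genes
    mid_bp <- sort(floor(stats::runif(n, 0, L_bp)))
    len <- pmin(6000, pmax(min_len,
                           round(stats::rgamma(n, shape = 2.5, scale = 380))))
    start0 <- (mid_bp - floor(len / 2)) %% L_bp     # 0-based
    end0 <- (start0 + len - 1) %% L_bp
    ann <- data.frame(
      gene = sprintf("g%05d", seq_len(n)),
      start_bp = start0 + 1L,
      end_bp = end0 + 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      essential = stats::rbinom(n, 1L, config$essential_fraction),
      category = sample(names(config$category_labels), n, replace = TRUE,
                        prob = config$category_labels),
      stringsAsFactors = FALSE)
    ann$midpoint_kb <- gene_midpoint_kb(ann, config$genome_length_kb)
    ann
  })
}

#' Circular midpoint of annotated genes, in kb
#'
#' Converts 1-based inclusive bp intervals to midpoints on the circular
#' coordinate [0, L) kb. Genes whose end precedes their start wrap across
#' the origin and their midpoint is computed modulo the genome length.
#'
#' @param annotation annotation data.frame with `start_bp`, `end_bp`.
#' @param genome_length_kb circular genome length, kb.
#' @return numeric vector of midpoints in [0, genome_length_kb).
#' @export
gene_midpoint_kb <- function(annotation, genome_length_kb) {
  L_bp <- round(genome_length_kb * 1000)
  s <- annotation$start_bp - 1   # 0-based
  e <- annotation$end_bp - 1
  len <- ifelse(e >= s, e - s + 1, L_bp - s + e + 1)
  ((s + (len - 1) / 2) %% L_bp) / 1000
}

#' Generate a wild-type expression table for one medium
#'
#' Per-gene log10 RPKM is a baseline plus a positional cosine over the
#' circular genome (`n_periods` cycles, amplitude
#' `positional_amplitude_expr`), a gene-specific effect, and independent
#' replicate noise.
#'
#' @param annotation output of [generate_annotation()].
#' @param config a [synthetic_config()].
#' @param medium medium label; must be a name of `config$media`.
#' @return data.frame with `gene`, `medium`, replicate columns `rep1..repN`,
#'   and `mean`. The per-gene positional and gene-effect components are
#'   attached as attributes `positional` and `gene_effect`.
#' @export
generate_expression <- function(annotation, config, medium) {
  validate_synthetic_config(config)
  m_idx <- match(medium, names(config$media))
  if (is.na(m_idx)) stop("unknown medium: ", medium)
  L <- config$genome_length_kb
  x <- annotation$midpoint_kb
  pos <- config$positional_amplitude_expr *
    cos(2 * pi * config$n_periods * x / L + config$positional_phase)
  with_local_seed(derive_seed(config$seed, "expression") + m_idx, {
    n <- nrow(annotation)
    eff <- stats::rnorm(n, 0, config$gene_effect_sd)
    reps <- vapply(seq_len(config$n_replicates), function(r)
      config$baseline_expr + pos + eff +
        stats::rnorm(n, 0, config$expression_sd),
      numeric(n))
    reps <- matrix(reps, nrow = n)
    colnames(reps) <- paste0("rep", seq_len(config$n_replicates))
    out <- data.frame(gene = annotation$gene, medium = medium,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(reps))
    out$mean <- rowMeans(reps)
    attr(out, "positional") <- pos
    attr(out, "gene_effect") <- eff
    out
  })
}

#' Generate true knockout growth rates coupled to expression
#'
#' The true exponential rate of the strain lacking gene g is the wild-type
#' rate minus a positional cosine locked in antiphase with the expression
#' positional component, minus a calibrated multiple of the gene's centred
#' mean expression, plus a gene-level residual. The coupling coefficient is
#' solved by bisection so that the realized Spearman correlation between
#' mean expression and true growth rate over the non-essential genes hits
#' `target_rho` within +/- 0.05 (the calibration stops at +/- 0.02).
#' Essential genes carry a true rate but are flagged so downstream stages
#' can exclude them or set them to zero.
#'
#' @param annotation output of [generate_annotation()].
#' @param expression output of [generate_expression()] for the same
#'   annotation and medium.
#' @param config a [synthetic_config()].
#' @param medium medium label.
#' @return data.frame with `gene`, `medium`, `essential`, `mu_true` (h^-1);
#'   attributes `beta` (calibrated coupling), `realized_rho`, and
#'   `positional` (the per-gene growth positional component, antiphase to
#'   the expression one).
#' @export
generate_growth_truth <- function(annotation, expression, config, medium) {
  validate_synthetic_config(config)
  m_idx <- match(medium, names(config$media))
  if (is.na(m_idx)) stop("unknown medium: ", medium)
  if (!identical(annotation$gene, expression$gene))
    stop("expression was not generated for this annotation")
  mu_wt <- config$media[[medium]]$mu
  L <- config$genome_length_kb
  x <- annotation$midpoint_kb
  pos <- config$positional_amplitude_growth *
    cos(2 * pi * config$n_periods * x / L + config$positional_phase)
  e_c <- expression$mean - mean(expression$mean)
  nonsel <- annotation$essential == 0L
  with_local_seed(derive_seed(config$seed, "growth_truth") + m_idx, {
    resid <- stats::rnorm(nrow(annotation), 0, config$growth_residual_sd)
    mu_of <- function(beta) mu_wt - pos - beta * e_c + resid
    rho_of <- function(beta) {
      mu <- mu_of(beta)[nonsel]
      e <- expression$mean[nonsel]
      if (stats::sd(mu) == 0 || stats::sd(e) == 0) return(0)
      stats::cor(e, mu, method = "spearman")
    }
    # rho(beta) decreases monotonically in beta; bracket then bisect
    span <- 10 * (stats::sd(mu_of(0)) + config$positional_amplitude_growth +
                    config$growth_residual_sd + 0.01) /
      max(stats::sd(e_c), 1e-12)
    lo <- -span; hi <- span
    r_lo <- rho_of(lo); r_hi <- rho_of(hi)
    target <- config$target_rho
    if (target > r_lo + 0.02 || target < r_hi - 0.02)
      stop(sprintf(
        "calibration failure: target_rho %.3f outside feasible range [%.3f, %.3f]",
        target, r_hi, r_lo))
    beta <- NA_real_
    for (i in seq_len(80)) {
      mid <- (lo + hi) / 2
      r_mid <- rho_of(mid)
      if (abs(r_mid - target) <= 0.02) { beta <- mid; break }
      if (r_mid > target) lo <- mid else hi <- mid
    }
    if (is.na(beta)) {
      beta <- (lo + hi) / 2
      if (abs(rho_of(beta) - target) > 0.05)
        stop("calibration failure: bisection did not reach target_rho")
    }
    out <- data.frame(gene = annotation$gene, medium = medium,
                      essential = annotation$essential,
                      mu_true = mu_of(beta), stringsAsFactors = FALSE)
    attr(out, "beta") <- beta
    attr(out, "realized_rho") <- rho_of(beta)
    attr(out, "positional") <- -pos   # growth positional component
    out
  })
}

#' Assign strains and replicates to plates and wells
#'
#' Fills 96-well plates in row-major well order, one plate series per
#' replicate, rotating the within-plate well slot by 37 positions per
#' replicate (37 is coprime with 96) so that the replicates of a strain
#' always sit in different well locations.
#'
#' @param strains character vector of strain (gene) ids.
#' @param n_replicates replicates per strain.
#' @return data.frame `strain`, `replicate`, `plate`, `well`.
#' @export
plate_layout <- function(strains, n_replicates = 3L) {
  rows <- LETTERS[1:8]; cols <- 1:12
  wells <- as.vector(t(outer(rows, cols, paste0)))  # A1..A12, B1..B12, ...
  n <- length(strains)
  n_plates <- ceiling(n / 96)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    slot <- (seq_len(n) - 1L + (r - 1L) * 37L) %% 96L
    plate <- (seq_len(n) - 1L) %/% 96L + 1L + (r - 1L) * n_plates
    data.frame(strain = strains, replicate = r,
               plate = plate, well = wells[slot + 1L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate plate-reader growth curves from true knockout rates
#'
#' Each strain x replicate well receives a logistic curve
#' `OD(t) = K_w / (1 + ((K_w - OD0)/OD0) exp(-mu t))` sampled on the
#' configured time grid, where the carrying capacity `K_w = K +
#' well_bias_slope * serpentine index` carries the well-location bias (the
#' rate never does). Readings are the blank offset plus the logistic value
#' plus Gaussian noise, truncated below at the blank floor. Essential genes
#' are excluded: no knockout strain exists for them.
#'
#' @param truth output of [generate_growth_truth()].
#' @param config a [synthetic_config()].
#' @param layout optional layout from [plate_layout()]; defaults to the
#'   package layout over the non-essential strains.
#' @return list with `curves` (list of `growth_curve` objects) and
#'   `well_map` (data.frame `plate`, `well`, `strain`, `medium`,
#'   `replicate`).
#' @export
generate_plate_curves <- function(truth, config, layout = NULL) {
  validate_synthetic_config(config)
  medium <- truth$medium[1]
  strains <- truth$gene[truth$essential == 0L]
  if (is.null(layout)) layout <- plate_layout(strains, config$n_replicates)
  if (anyDuplicated(layout[c("plate", "well")]))
    stop("layout assigns the same well twice on one plate")
  if (!all(layout$strain %in% strains))
    stop("layout names strains absent from the truth table")
  K <- config$media[[medium]]$K
  mu_true <- truth$mu_true[match(layout$strain, truth$gene)]
  times <- seq(0, config$duration_h, by = config$interval_h)
  widx <- serpentine_index(layout$well)
  m_idx <- match(medium, names(config$media))
  with_local_seed(derive_seed(config$seed, "plates") + m_idx, {
    mu_rep <- mu_true + stats::rnorm(nrow(layout), 0, config$growth_replicate_sd)
    curves <- lapply(seq_len(nrow(layout)), function(i) {
      Kw <- K + config$well_bias_slope * widx[i]
      mu <- max(mu_rep[i], 0)
      od <- if (mu == 0) rep(config$od0, length(times)) else
        Kw / (1 + ((Kw - config$od0) / config$od0) * exp(-mu * times))
      reading <- config$blank + od +
        stats::rnorm(length(times), 0, config$od_sd)
      reading <- pmax(reading, config$blank)
      growth_curve(strain = layout$strain[i], medium = medium,
                   replicate = layout$replicate[i], plate = layout$plate[i],
                   well = layout$well[i], times = times, od = reading,
                   blank = config$blank)
    })
    well_map <- data.frame(plate = layout$plate, well = layout$well,
                           strain = layout$strain, medium = medium,
                           replicate = layout$replicate,
                           stringsAsFactors = FALSE)
    list(curves = curves, well_map = well_map)
  })
}
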