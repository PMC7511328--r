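#' Default analysis parameters for the pipeline
#'
#' @return named list of analysis parameters: rate-window size, positivity
#'   floor, periodicity window and bin step (kb), permutation and shuffle
#'   counts, q threshold, category size cutoff, positional-signal mode,
#'   and master seed.
#' @export
pipeline_params <- function() {
  list(rate_window = 5L, floor = 0.003, window_kb = 100, bin_step_kb = 1,
       n_perm = 1000L, n_shuffles = 1000L, q_threshold = 0.05,
       min_genes = 30L, mode = "essential_zero", exclude_k1 = TRUE,
       seed = 1L)
}

#' Run the full analysis pipeline
#'
#' Orchestrates growth-rate estimation, fitness classification and
#' enrichment, expression normalization, rank-product DEG/DGG detection,
#' growth-expression association, and chromosomal periodicity, writing all
#' result tables as TSV plus a JSON manifest into `out_dir`. Input is
#' either a [synthetic_config()] (`config$synthetic`) or file paths
#' (`config$annotation`, `config$well_map`, `config$plate_csvs` as a named
#' vector keyed by plate id, `config$expression` as a named vector keyed by
#' medium). When expression input is absent the expression-dependent stages
#' are skipped with a notice. Any stage error aborts the run with the stage
#' name; tables written before the failure are preserved.
#'
#' @param config list: `out_dir`, input source as above, `media` (two
#'   labels for the between-media comparison; defaults to the media found),
#'   and any overrides of [pipeline_params()] under `params`.
#' @return the manifest (invisibly), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par <- utils::modifyList(pipeline_params(), config$params %||% list())
  log_lines <- character(0)
  stages <- list()
  note <- function(stage, status, ...) {
    kv <- c(...)
    line <- paste0("stage=", stage, " status=", status,
                   if (length(kv)) paste0(" ", paste(names(kv), kv,
                                                     sep = "=",
                                                     collapse = " ")))
    log_lines <<- c(log_lines, line)
    stages[[stage]] <<- c(list(status = status), as.list(kv))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, "error", message = conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs -------------------------------------------------------------
  synthetic <- !is.null(config$synthetic)
  if (synthetic) {
    cfg <- config$synthetic
    ann <- generate_annotation(cfg)
    L <- cfg$genome_length_kb
    media <- config$media %||% names(cfg$media)
    expr_tabs <- lapply(media, function(m) generate_expression(ann, cfg, m))
    names(expr_tabs) <- media
    truth <- lapply(media, function(m)
      generate_growth_truth(ann, expr_tabs[[m]], cfg, m))
    names(truth) <- media
    plates <- lapply(media, function(m) generate_plate_curves(truth[[m]], cfg))
    curves <- unlist(lapply(plates, `[[`, "curves"), recursive = FALSE)
    write_annotation(ann, file.path(out_dir, "annotation.tsv"), L)
    note("inputs", "ok", source = "synthetic", genes = nrow(ann))
  } else {
    ann <- run_stage("inputs", read_annotation(config$annotation))
    L <- attr(ann, "genome_length_kb")
    wm <- run_stage("inputs", read_well_map(config$well_map))
    curves <- run_stage("inputs", unlist(lapply(names(config$plate_csvs),
      function(pl) read_plate_csv(config$plate_csvs[[pl]], wm, pl)),
      recursive = FALSE))
    expr_tabs <- NULL
    if (!is.null(config$expression)) {
      expr_tabs <- lapply(config$expression, read_expression_tsv)
      names(expr_tabs) <- names(config$expression)
    }
    media <- config$media %||% unique(vapply(curves, `[[`, "", "medium"))
    note("inputs", "ok", source = "files", genes = nrow(ann),
         curves = length(curves))
  }

  # ---- growth -------------------------------------------------------------
  est <- run_stage("growth", estimate_growth_rates(curves,
                                                   window = par$rate_window,
                                                   floor = par$floor))
  rate_table <- run_stage("growth", aggregate_replicates(est))
  write_tsv(rate_table, file.path(out_dir, "rate_table.tsv"))
  note("growth", "ok", curves = length(curves), strains = nrow(rate_table),
       no_growth = attr(rate_table, "n_no_growth_replicates"))

  # ---- classification / enrichment ---------------------------------------
  assignments <- run_stage("classification", lapply(media, function(m)
    classify_genes(rate_table, m)))
  names(assignments) <- media
  nonessential <- ann$gene[ann$essential == 0L]
  enrich <- run_stage("classification", lapply(media, function(m) {
    sel <- assignments[[m]]$strain[assignments[[m]]$class == "very_positive"]
    if (length(sel)) binomial_enrichment(sel, ann, background = nonessential)
    else NULL
  }))
  names(enrich) <- media
  for (m in media) {
    write_tsv(assignments[[m]],
              file.path(out_dir, paste0("classes_", m, ".tsv")))
    if (!is.null(enrich[[m]]))
      write_tsv(enrich[[m]],
                file.path(out_dir, paste0("enrichment_very_positive_", m,
                                          ".tsv")))
  }
  note("classification", "ok",
       very_positive = paste(vapply(media, function(m)
         sum(assignments[[m]]$class == "very_positive"), numeric(1)),
         collapse = "/"))

  # ---- expression-dependent stages ---------------------------------------
  have_expr <- !is.null(expr_tabs) && all(media[1:2] %in% names(expr_tabs))
  if (have_expr) {
    norm <- run_stage("normalization", global_normalize(expr_tabs[media]))
    note("normalization", "ok",
         target_median = signif(attr(norm, "target_median"), 6))

    # DEG: expression replicates between the first two media
    rp_deg <- run_stage("differential", {
      a <- norm[[media[1]]]; b <- norm[[media[2]]]
      shared <- intersect(a$gene, b$gene)
      rc_a <- grep("^rep[0-9]+$", names(a), value = TRUE)
      rc_b <- grep("^rep[0-9]+$", names(b), value = TRUE)
      ma <- as.matrix(a[match(shared, a$gene), rc_a])
      mb <- as.matrix(b[match(shared, b$gene), rc_b])
      rownames(ma) <- rownames(mb) <- shared
      rank_product(ma, mb, n_perm = par$n_perm, seed = par$seed)
    })
    degs <- attr(identify_significant(rp_deg, par$q_threshold), "ids")
    write_tsv(rp_deg, file.path(out_dir, "rank_product_expression.tsv"))

    # DGG: replicate growth rates between the two media
    rp_dgg <- run_stage("differential", {
      mats <- lapply(media[1:2], function(m) {
        e <- est[est$medium == m & !est$no_growth, ]
        reps <- sort(unique(e$replicate))
        strains <- Reduce(intersect, lapply(reps, function(r)
          e$strain[e$replicate == r]))
        mm <- vapply(reps, function(r)
          e$mu[e$replicate == r][match(strains, e$strain[e$replicate == r])],
          numeric(length(strains)))
        mm <- matrix(mm, nrow = length(strains),
                     dimnames = list(strains, NULL))
        mm
      })
      shared <- intersect(rownames(mats[[1]]), rownames(mats[[2]]))
      rank_product(mats[[1]][shared, , drop = FALSE],
                   mats[[2]][shared, , drop = FALSE],
                   n_perm = par$n_perm, seed = par$seed + 1L)
    })
    dggs <- attr(identify_significant(rp_dgg, par$q_threshold), "ids")
    write_tsv(rp_dgg, file.path(out_dir, "rank_product_growth.tsv"))
    venn <- deg_dgg_overlap(degs, dggs, unique(rp_deg$id), unique(rp_dgg$id))
    note("differential", "ok", degs = length(degs), dggs = length(dggs),
         overlap = venn$both)

    # association
    assoc <- run_stage("association", lapply(media, function(m) {
      j <- join_growth_expression(rate_table, norm[[m]], ann, m)
      write_tsv(j, file.path(out_dir, paste0("join_", m, ".tsv")))
      sp <- spearman_growth_expression(j)
      rnd <- if (nrow(j) >= 10)
        randomization_test(j, n_shuffles = par$n_shuffles,
                           seed = par$seed) else NULL
      list(join = j, spearman = sp, randomization = rnd)
    }))
    names(assoc) <- media
    note("association", "ok",
         rho = paste(vapply(assoc, function(a) signif(a$spearman$rho, 3),
                            numeric(1)), collapse = "/"))
  } else {
    note("normalization", "skipped", reason = "no expression input")
    note("differential", "skipped", reason = "no expression input")
    note("association", "skipped", reason = "no expression input")
    degs <- dggs <- NULL; venn <- NULL; assoc <- NULL
  }

  # ---- periodicity --------------------------------------------------------
  period <- run_stage("periodicity", lapply(media, function(m) {
    mu <- stats::setNames(rep(0, nrow(ann)), ann$gene)
    hit <- match(rate_table$strain[rate_table$medium == m], ann$gene)
    mu[hit] <- rate_table$mean_mu[rate_table$medium == m]
    sig <- positional_signal(ann, mu, L, mode = par$mode,
                             bin_step = par$bin_step_kb,
                             window = par$window_kb)
    dom <- dominant_period(sig, exclude_k1 = par$exclude_k1)
    pg <- periodogram(sig)
    write_tsv(data.frame(anchor_kb = sig$anchors_kb, value = sig$values),
              file.path(out_dir, paste0("growth_signal_", m, ".tsv")))
    write_tsv(data.frame(k = pg$k, wavelength_kb = pg$wavelength,
                         power = pg$power),
              file.path(out_dir, paste0("periodogram_growth_", m, ".tsv")))
    ess <- ann[ann$essential == 1L, , drop = FALSE]
    dens_cor <- NULL
    if (nrow(ess)) {
      ness_sig <- positional_signal(ann, mu, L, mode = "nonessential_only",
                                    bin_step = par$bin_step_kb,
                                    window = par$window_kb)
      dens <- positional_signal(ess, genome_length_kb = L, mode = "density",
                                bin_step = par$bin_step_kb,
                                window = par$window_kb)
      dens_cor <- tryCatch(essential_density_correlation(ness_sig, dens),
                           error = function(e) NULL)
    }
    list(dominant = dom, density_correlation = dens_cor)
  }))
  names(period) <- media
  note("periodicity", "ok",
       wavelength_kb = paste(vapply(period, function(p)
         round(p$dominant$wavelength, 1), numeric(1)), collapse = "/"))

  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package = "chromogrowth",
    version = as.character(utils::packageVersion("chromogrowth")),
    parameters = par,
    seed = par$seed,
    media = media,
    stages = stages,
    results = list(
      n_strains = nrow(rate_table),
      very_positive = lapply(assignments, function(a)
        sum(a$class == "very_positive")),
      degs = if (have_expr) length(degs) else NULL,
      dggs = if (have_expr) length(dggs) else NULL,
      deg_dgg_overlap = if (have_expr) venn$both else NULL,
      spearman_rho = if (have_expr)
        lapply(assoc, function(a) a$spearman$rho) else NULL,
      dominant_wavelength_kb = lapply(period, function(p)
        p$dominant$wavelength),
      fisher_g = lapply(period, function(p) p$dominant$g)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(manifest)
}
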