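# File formats consumed and produced by the pipeline:
#  - annotation TSV: gene, start_bp, end_bp, strand, essential{0,1},
#    category; genome length on a leading "#genome_length_kb=" line
#  - plate-reader wide CSV: time_h column + one column per well (A1..H12)
#  - well-map CSV: plate, well, strain, medium, replicate (strain "BLANK"
#    marks blank wells)
#  - expression TSV: gene, medium, rep1..repN
#  - config: flat YAML

#' Read a gene annotation TSV
#'
#' Expects columns `gene`, `start_bp`, `end_bp`, `strand`, `essential`,
#' `category`; coordinates are 1-based inclusive bp on a circular genome,
#' and genes whose end precedes their start wrap across the origin. The
#' genome length is taken from a leading `#genome_length_kb=<L>` line or
#' from the argument.
#'
#' @param path file path.
#' @param genome_length_kb genome length override, kb.
#' @return annotation data.frame with `midpoint_kb` added; genome length
#'   in attribute `genome_length_kb`.
#' @export
read_annotation <- function(path, genome_length_kb = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*genome_length_kb\\s*=", first)) {
    L_file <- as.numeric(sub("^#\\s*genome_length_kb\\s*=\\s*", "", first))
    genome_length_kb <- genome_length_kb %||% L_file
  }
  if (is.null(genome_length_kb))
    stop("genome length not given and no #genome_length_kb= header found")
  ann <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("gene", "start_bp", "end_bp", "strand", "essential", "category")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene))
    stop("duplicate gene id: ", ann$gene[duplicated(ann$gene)][1])
  L_bp <- round(genome_length_kb * 1000)
  bad <- ann$start_bp < 1 | ann$start_bp > L_bp |
    ann$end_bp < 1 | ann$end_bp > L_bp
  if (any(bad)) stop("coordinates out of [1, ", L_bp, "] for gene(s): ",
                     paste(utils::head(ann$gene[bad], 5), collapse = ", "))
  ann$essential <- as.integer(ann$essential)
  ann$midpoint_kb <- gene_midpoint_kb(ann, genome_length_kb)
  attr(ann, "genome_length_kb") <- genome_length_kb
  ann
}

#' Write a gene annotation TSV
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @param genome_length_kb genome length recorded in the header line.
#' @export
write_annotation <- function(annotation, path, genome_length_kb) {
  cols <- c("gene", "start_bp", "end_bp", "strand", "essential", "category")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#genome_length_kb=%g", genome_length_kb), con)
  utils::write.table(annotation[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a well map CSV
#'
#' @param path file path; columns `plate`, `well`, `strain`, `medium`,
#'   `replicate`.
#' @return data.frame.
#' @export
read_well_map <- function(path) {
  wm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "strain", "medium", "replicate")
  miss <- setdiff(need, names(wm))
  if (length(miss)) stop("well map missing column(s): ",
                         paste(miss, collapse = ", "))
  wm
}

#' @rdname read_well_map
#' @param well_map well map data.frame.
#' @export
write_well_map <- function(well_map, path) {
  utils::write.csv(well_map, path, row.names = FALSE, quote = FALSE)
}

#' Read a plate-reader wide CSV into growth curves
#'
#' The CSV has a `time_h` column plus one column per well. Wells mapped to
#' strain `"BLANK"` supply the per-plate blank (the mean of their first
#' readings) and are not emitted as curves; unmapped wells are skipped and
#' counted in the `n_unmapped` attribute.
#'
#' @param path CSV path for one plate.
#' @param well_map well map data.frame (see [read_well_map()]).
#' @param plate plate id of this CSV within the map.
#' @return list of [growth_curve()] objects; blank value in attribute
#'   `blank`.
#' @export
read_plate_csv <- function(path, well_map, plate) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time_h" %in% names(tab)) stop("plate CSV lacks a time_h column")
  if (!is.numeric(tab$time_h) || any(diff(tab$time_h) <= 0))
    stop("time_h must be numeric and strictly increasing")
  for (cn in setdiff(names(tab), "time_h"))
    if (!is.numeric(tab[[cn]]))
      stop("non-numeric readings in column ", cn)
  wm <- well_map[well_map$plate == plate, , drop = FALSE]
  absent <- setdiff(wm$well, names(tab))
  if (length(absent))
    stop("mapped well(s) absent from CSV: ", paste(absent, collapse = ", "))
  blanks <- wm$well[wm$strain == "BLANK"]
  blank <- if (length(blanks))
    mean(vapply(blanks, function(w) tab[[w]][1], numeric(1))) else 0
  wm <- wm[wm$strain != "BLANK", , drop = FALSE]
  curves <- lapply(seq_len(nrow(wm)), function(i)
    growth_curve(strain = wm$strain[i], medium = wm$medium[i],
                 replicate = wm$replicate[i], plate = plate,
                 well = wm$well[i], times = tab$time_h,
                 od = tab[[wm$well[i]]], blank = blank))
  attr(curves, "blank") <- blank
  attr(curves, "n_unmapped") <- length(setdiff(names(tab),
                                               c("time_h", well_map$well)))
  curves
}

#' Write growth curves of one plate as a wide CSV
#'
#' @param curves list of [growth_curve()] objects sharing one time grid.
#' @param path output path.
#' @export
write_plate_csv <- function(curves, path) {
  times <- curves[[1]]$times
  tab <- data.frame(time_h = times)
  for (cu in curves) {
    if (!isTRUE(all.equal(cu$times, times)))
      stop("curves do not share one time grid")
    tab[[cu$well]] <- cu$od
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
}

#' Read / write an expression TSV
#'
#' Columns `gene`, `medium`, `rep1..repN`; `mean` is recomputed on read.
#'
#' @param path file path.
#' @return expression data.frame.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rc <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  if (!all(c("gene", "medium") %in% names(tab)) || !length(rc))
    stop("expression TSV needs gene, medium and rep1..repN columns")
  tab$mean <- rowMeans(as.matrix(tab[rc]))
  tab
}

#' @rdname read_expression_tsv
#' @param expression expression data.frame.
#' @export
write_expression_tsv <- function(expression, path) {
  keep <- c("gene", "medium", grep("^rep[0-9]+$", names(expression),
                                   value = TRUE))
  utils::write.table(expression[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a generic result table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read / write a flat YAML configuration
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) yaml::write_yaml(config, path)
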