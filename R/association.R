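#' Join knockout growth rates with wild-type expression
#'
#' Inner join on gene id between a rate table and an expression table for
#' one medium, carrying the functional category from the annotation.
#' Duplicate ids in either table are an error; unmatched ids are counted in
#' attributes.
#'
#' @param rate_table a [aggregate_replicates()] table.
#' @param expression_table expression data.frame (`gene`, `medium`,
#'   `mean`).
#' @param annotation annotation data.frame (`gene`, `category`).
#' @param medium medium label to subset both tables on.
#' @return data.frame `gene`, `medium`, `mu`, `expression`, `category`;
#'   attributes `n_unmatched_growth`, `n_unmatched_expression`.
#' @export
join_growth_expression <- function(rate_table, expression_table, annotation,
                                   medium) {
  rt <- rate_table[rate_table$medium == medium, , drop = FALSE]
  et <- expression_table[expression_table$medium == medium, , drop = FALSE]
  if (anyDuplicated(rt$strain))
    stop("duplicate strain in rate table: ",
         rt$strain[duplicated(rt$strain)][1])
  if (anyDuplicated(et$gene))
    stop("duplicate gene in expression table: ",
         et$gene[duplicated(et$gene)][1])
  shared <- intersect(rt$strain, et$gene)
  if (!length(shared)) stop("no shared gene ids between growth and expression")
  out <- data.frame(gene = shared, medium = medium,
                    mu = rt$mean_mu[match(shared, rt$strain)],
                    expression = et$mean[match(shared, et$gene)],
                    category = annotation$category[match(shared,
                                                         annotation$gene)],
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched_growth") <- nrow(rt) - length(shared)
  attr(out, "n_unmatched_expression") <- nrow(et) - length(shared)
  out
}

#' Spearman correlation between knockout growth and wild-type expression
#'
#' @param join a [join_growth_expression()] table.
#' @param medium optional medium label to subset on.
#' @return list with `rho`, `p`, and `n`.
#' @export
spearman_growth_expression <- function(join, medium = NULL) {
  if (!is.null(medium)) join <- join[join$medium == medium, , drop = FALSE]
  res <- spearman_cor(join$expression, join$mu)
  res$n <- nrow(join)
  res
}

#' Randomization test of the growth-expression correlation
#'
#' Shuffles one column of the join (growth rates, expression, or both in
#' turn) `n_shuffles` times, recomputing the Spearman correlation for each
#' shuffle, and reports the empirical two-sided p with the add-one
#' convention `p = (#\{|rho_null| >= |rho_obs|\} + 1) / (n_shuffles + 1)`.
#'
#' @param join a [join_growth_expression()] table.
#' @param n_shuffles number of shuffles (default 1000; a warning is issued
#'   below 100).
#' @param shuffle which column(s) to randomize: `"growth"`,
#'   `"expression"`, or `"both"` (both run separately; default).
#' @param seed integer seed.
#' @return data.frame with one row per shuffled column: `shuffled`,
#'   `rho_obs`, `p_empirical`, `null_mean`, `null_sd`; null distributions
#'   in attribute `null_rho` (named list).
#' @export
randomization_test <- function(join, n_shuffles = 1000L,
                               shuffle = c("both", "growth", "expression"),
                               seed = 1L) {
  shuffle <- match.arg(shuffle)
  if (nrow(join) < 10L) stop("need >= 10 rows for a randomization test")
  if (n_shuffles < 100L) warning("n_shuffles < 100: empirical p is coarse")
  cols <- if (shuffle == "both") c("growth", "expression") else shuffle
  rho_obs <- stats::cor(join$expression, join$mu, method = "spearman")
  nulls <- list()
  rows <- lapply(seq_along(cols), function(ci) {
    nr <- with_local_seed(derive_seed(seed, "shuffle") + ci, {
      vapply(seq_len(n_shuffles), function(i) {
        if (cols[ci] == "growth")
          stats::cor(join$expression, sample(join$mu), method = "spearman")
        else
          stats::cor(sample(join$expression), join$mu, method = "spearman")
      }, numeric(1))
    })
    nulls[[cols[ci]]] <<- nr
    data.frame(shuffled = cols[ci], rho_obs = rho_obs,
               p_empirical = (sum(abs(nr) >= abs(rho_obs)) + 1) /
                 (n_shuffles + 1),
               null_mean = mean(nr), null_sd = stats::sd(nr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null_rho") <- nulls
  out
}

#' Category-level growth-expression correlation
#'
#' Retains functional categories with more than `min_genes` genes,
#' averages growth rate and expression within each, and computes the
#' Spearman correlation across the category means, plus the within-category
#' correlation for every retained category.
#'
#' @param join a [join_growth_expression()] table.
#' @param min_genes categories must exceed this gene count (default 30).
#' @return list with `category_means` (data.frame `category`, `n`,
#'   `mean_mu`, `mean_expression`), `across` (list `rho`, `p`, `n`), and
#'   `within` (data.frame `category`, `n`, `rho`, `p`).
#' @export
category_level_correlation <- function(join, min_genes = 30L) {
  sizes <- table(join$category)
  keep <- names(sizes)[sizes > min_genes]
  if (!length(keep)) stop("no category exceeds min_genes = ", min_genes)
  cm <- do.call(rbind, lapply(keep, function(cc) {
    g <- join[join$category == cc, ]
    data.frame(category = cc, n = nrow(g), mean_mu = mean(g$mu),
               mean_expression = mean(g$expression),
               stringsAsFactors = FALSE)
  }))
  across <- spearman_cor(cm$mean_expression, cm$mean_mu)
  across$n <- nrow(cm)
  within <- do.call(rbind, lapply(keep, function(cc) {
    g <- join[join$category == cc, ]
    w <- tryCatch(spearman_cor(g$expression, g$mu),
                  error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(category = cc, n = nrow(g), rho = w$rho, p = w$p,
               stringsAsFactors = FALSE)
  }))
  list(category_means = cm, across = across, within = within)
}
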