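#' Five-class fitness classification of knockout strains
#'
#' Classifies each gene by the growth rate of the strain lacking it,
#' against the box-plot geometry of the medium's rate distribution:
#' quartiles Q1/Q3 (linear-interpolation, type-7 convention) and the 1.5
#' IQR fences. Class semantics invert the rate, because a fast-growing
#' knockout means the missing gene was costly: rate above the upper fence
#' is `very_negative` (gene contribution), between Q3 and the upper fence
#' `negative`, within the quartile box `neutral`, between the lower fence
#' and Q1 `positive`, below the lower fence `very_positive`. Boundary
#' values go to the inner (more neutral) class.
#'
#' @param rate_table a [aggregate_replicates()] table.
#' @param medium medium label.
#' @return data.frame with `strain`, `medium`, `mu`, `class`; quartiles and
#'   fences in attributes `q1`, `q3`, `lower_fence`, `upper_fence`.
#' @export
classify_genes <- function(rate_table, medium) {
  rt <- rate_table[rate_table$medium == medium, , drop = FALSE]
  if (!nrow(rt)) stop("empty rate table for medium ", medium)
  if (nrow(rt) < 5L) stop("need >= 5 strains to place quartile fences")
  r <- rt$mean_mu
  q <- stats::quantile(r, c(0.25, 0.75), type = 7, names = FALSE)
  q1 <- q[1]; q3 <- q[2]
  iqr <- q3 - q1
  lf <- q1 - 1.5 * iqr
  uf <- q3 + 1.5 * iqr
  cls <- ifelse(r > uf, "very_negative",
         ifelse(r > q3, "negative",
         ifelse(r >= q1, "neutral",
         ifelse(r >= lf, "positive", "very_positive"))))
  out <- data.frame(strain = rt$strain, medium = medium, mu = r,
                    class = factor(cls, levels = c(
                      "very_negative", "negative", "neutral",
                      "positive", "very_positive")),
                    stringsAsFactors = FALSE)
  attr(out, "q1") <- q1; attr(out, "q3") <- q3
  attr(out, "lower_fence") <- lf; attr(out, "upper_fence") <- uf
  out
}

#' Binomial over-representation test of functional categories
#'
#' For each category with m genes among the M background genes, the count
#' x observed in the n selected genes is tested against
#' X ~ Binomial(n, m/M): p = P(X >= x), one-sided for over-representation,
#' Bonferroni-corrected over the number of categories actually tested.
#' Categories absent from the background are skipped with a warning.
#'
#' @param selected character vector of selected gene ids.
#' @param annotation annotation data.frame (`gene`, `category`).
#' @param background optional character vector of background gene ids
#'   (defaults to all annotated genes). Use the non-essential genes when
#'   the selection was drawn from a knockout library.
#' @return data.frame `category`, `m`, `x`, `n`, `M`, `p`, `p_bonferroni`,
#'   ordered by p.
#' @export
binomial_enrichment <- function(selected, annotation, background = NULL) {
  background <- background %||% annotation$gene
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background")
  cat_of <- annotation$category[match(background, annotation$gene)]
  cats <- sort(unique(annotation$category))
  m_all <- table(factor(cat_of, levels = cats))
  if (any(m_all == 0)) {
    warning("skipping categories absent from background: ",
            paste(cats[m_all == 0], collapse = ", "))
    cats <- cats[m_all > 0]
  }
  n <- length(selected)
  M <- length(background)
  sel_cat <- annotation$category[match(selected, annotation$gene)]
  rows <- lapply(cats, function(cc) {
    m <- sum(cat_of == cc)
    x <- sum(sel_cat == cc)
    p <- if (x == 0) 1 else
      stats::pbinom(x - 1, n, m / M, lower.tail = FALSE)
    data.frame(category = cc, m = m, x = x, n = n, M = M, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p, out$category), ]
}

#' Overlap of a fitness class between two media
#'
#' @param assignments_a,assignments_b [classify_genes()] outputs for the
#'   two media.
#' @param class class label to compare (e.g. `"very_positive"`).
#' @return list with `only_a`, `only_b`, `both` counts and the gene id
#'   vectors `genes_only_a`, `genes_only_b`, `genes_both`.
#' @export
class_overlap <- function(assignments_a, assignments_b, class) {
  a <- assignments_a$strain[assignments_a$class == class]
  b <- assignments_b$strain[assignments_b$class == class]
  list(only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)),
       both = length(intersect(a, b)),
       genes_only_a = setdiff(a, b),
       genes_only_b = setdiff(b, a),
       genes_both = intersect(a, b))
}

#' Statistical re-evaluation of non-neutral class calls
#'
#' Retains a non-neutral class call only when the strain's replicate rates
#' differ significantly from the medium's median rate by a two-sided
#' one-sample t test at level `alpha`; otherwise the strain is demoted to
#' neutral. Strains with fewer than two grown replicates cannot be tested
#' and are exempt from demotion (flagged `untestable`).
#'
#' @param assignments [classify_genes()] output.
#' @param estimates replicate-level estimates from
#'   [estimate_growth_rates()].
#' @param alpha significance level (default 0.05).
#' @return the assignment data.frame with updated `class` plus columns
#'   `demoted` and `untestable`.
#' @export
reevaluate_by_replicates <- function(assignments, estimates, alpha = 0.05) {
  med <- assignments$medium[1]
  est <- estimates[estimates$medium == med & !estimates$no_growth, ,
                   drop = FALSE]
  center <- stats::median(assignments$mu)
  out <- assignments
  out$demoted <- FALSE
  out$untestable <- FALSE
  for (i in which(out$class != "neutral")) {
    reps <- est$mu[est$strain == out$strain[i]]
    if (length(reps) < 2L) { out$untestable[i] <- TRUE; next }
    if (stats::sd(reps) == 0) next   # zero-variance replicates: keep call
    p <- stats::t.test(reps, mu = center)$p.value
    if (p >= alpha) {
      out$class[i] <- "neutral"
      out$demoted[i] <- TRUE
    }
  }
  out
}
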