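#' Global median normalization of expression tables
#'
#' Shifts each dataset by a constant so every dataset's median log10 RPKM
#' equals the grand target, the mean of the input medians. A constant shift
#' preserves within-dataset rank order exactly. Genes with no finite
#' replicate value in a dataset are dropped from it and listed in the
#' `dropped_genes` attribute.
#'
#' @param tables list of expression data.frames (`gene`, `medium`,
#'   `rep1..repN`, optionally `mean`).
#' @return list of normalized tables (per-gene `mean` recomputed); target
#'   median in attribute `target_median`.
#' @export
global_normalize <- function(tables) {
  if (!length(tables)) stop("no tables to normalize")
  rep_cols <- function(tab) grep("^rep[0-9]+$", names(tab), value = TRUE)
  meds <- vapply(tables, function(tab) {
    v <- unlist(tab[rep_cols(tab)])
    stats::median(v[is.finite(v)])
  }, numeric(1))
  target <- mean(meds)
  dropped <- character(0)
  out <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    rc <- rep_cols(tab)
    all_na <- !apply(is.finite(as.matrix(tab[rc])), 1, any)
    if (any(all_na)) {
      dropped <<- c(dropped, tab$gene[all_na])
      tab <- tab[!all_na, , drop = FALSE]
    }
    tab[rc] <- tab[rc] + (target - meds[i])
    tab$mean <- rowMeans(as.matrix(tab[rc]), na.rm = TRUE)
    tab
  })
  names(out) <- names(tables)
  attr(out, "target_median") <- target
  attr(out, "dropped_genes") <- unique(dropped)
  out
}

#' Rank-product differential statistic with permutation significance
#'
#' Identifies items (genes, or strains scored by growth rate) that differ
#' between two conditions A and B. For the unpaired two-class design every
#' replicate pair (i, j) contributes a comparison column of differences
#' `A[, i] - B[, j]` (log-space fold differences for expression; rate
#' differences for growth); `pairing = "all_pairs"` (default) uses all
#' R_A x R_B combinations, `"paired"` only replicate i against replicate i.
#' Within each column items are ranked with mid-ranks for ties — rank 1 is
#' the most A-biased item for the `up_in_A` direction and the most B-biased
#' for `up_in_B` — and the rank product is the geometric mean of an item's
#' ranks across columns. Significance comes from a pooled Monte-Carlo null
#' with `p = (# null RP <= observed + 1) / (n_perm * G + 1)`.
#'
#' Three null schemes are available. The default, `"iid_reference"`, draws
#' `n_perm` iid noise matrices with the same dimensions and pairing and
#' recomputes the rank products; because the statistic is rank-based this
#' is exactly the null law of the rank product under iid sampling,
#' including the dependence among all-pairs columns that share a replicate,
#' and planted effects cannot leak into it. `"column_shuffle"` is the
#' classical scheme that shuffles each column's ranks independently; it is
#' exact when the comparison columns are independent (paired design) but
#' anti-conservative for all-pairs columns. `"label_permutation"` redraws
#' the condition labels of the pooled replicates (one relabelling applied
#' to every item) and recomputes everything; it conditions on the observed
#' values but loses power when a sizable fraction of items carries strong
#' effects, since those effects re-enter the null tables. The native
#' rank-product FDR analogue pfp (`p * G / rank`, made monotone in p) is
#' reported as the primary q, with Benjamini-Hochberg alongside.
#'
#' @param values_a,values_b numeric matrices (items x replicates), same
#'   row order; rownames are item ids.
#' @param n_perm number of null draws (default 1000; a warning is issued
#'   below 100).
#' @param seed integer seed for the null stream.
#' @param null null scheme; see Details above.
#' @param pairing how replicate columns are combined into comparisons.
#' @return data.frame with `id`, `direction` (`up_in_A`/`up_in_B`), `RP`,
#'   `p`, `pfp_q`, `bh_q`.
#' @export
rank_product <- function(values_a, values_b, n_perm = 1000L, seed = 1L,
                         null = c("iid_reference", "column_shuffle",
                                  "label_permutation"),
                         pairing = c("all_pairs", "paired")) {
  null <- match.arg(null)
  pairing <- match.arg(pairing)
  A <- as.matrix(values_a); B <- as.matrix(values_b)
  if (nrow(A) != nrow(B)) stop("A and B must have the same items")
  G <- nrow(A)
  if (G < 2L) stop("need >= 2 items")
  if (ncol(A) < 1L || ncol(B) < 1L) stop("zero replicate columns")
  if (n_perm < 100L) warning("n_perm < 100: permutation p-values are coarse")
  ids <- rownames(A) %||% paste0("item", seq_len(G))
  nA <- ncol(A); nB <- ncol(B)
  if (pairing == "paired" && nA != nB)
    stop("paired comparisons need equal replicate counts; ",
         "use pairing = \"all_pairs\"")
  pairs <- if (pairing == "paired")
    data.frame(i = seq_len(nA), j = seq_len(nA))
  else expand.grid(i = seq_len(nA), j = seq_len(nB))
  K <- nrow(pairs)
  diff_cols <- function(a, b) {
    D <- vapply(seq_len(K), function(k) a[, pairs$i[k]] - b[, pairs$j[k]],
                numeric(G))
    matrix(D, nrow = G)
  }
  log_rp <- function(D, sign_mult)
    rowMeans(log(matrix(apply(-sign_mult * D, 2, rank), nrow = G)))
  D <- diff_cols(A, B)
  rp_obs <- lapply(c(1, -1), function(s) exp(log_rp(D, s)))

  null_log_rp <- with_local_seed(derive_seed(seed, "rankprod"), {
    up <- dn <- numeric(n_perm * G)
    if (null == "column_shuffle") {
      logR_up <- log(matrix(apply(-D, 2, rank), nrow = G))
      logR_dn <- log(matrix(apply(D, 2, rank), nrow = G))
      for (p_i in seq_len(n_perm)) {
        at <- ((p_i - 1L) * G + 1L):(p_i * G)
        acc_u <- acc_d <- rep(0, G)
        for (k in seq_len(K)) {
          acc_u <- acc_u + logR_up[sample.int(G), k]
          acc_d <- acc_d + logR_dn[sample.int(G), k]
        }
        up[at] <- acc_u / K; dn[at] <- acc_d / K
      }
    } else if (null == "iid_reference") {
      for (p_i in seq_len(n_perm)) {
        Xn <- matrix(stats::rnorm(G * (nA + nB)), G)
        Dp <- diff_cols(Xn[, seq_len(nA), drop = FALSE],
                        Xn[, nA + seq_len(nB), drop = FALSE])
        at <- ((p_i - 1L) * G + 1L):(p_i * G)
        up[at] <- log_rp(Dp, 1); dn[at] <- log_rp(Dp, -1)
      }
    } else {
      X <- cbind(A, B)
      for (p_i in seq_len(n_perm)) {
        idx <- sample.int(nA + nB)     # one relabelling for all items
        Dp <- diff_cols(X[, idx[seq_len(nA)], drop = FALSE],
                        X[, idx[nA + seq_len(nB)], drop = FALSE])
        at <- ((p_i - 1L) * G + 1L):(p_i * G)
        up[at] <- log_rp(Dp, 1); dn[at] <- log_rp(Dp, -1)
      }
    }
    list(sort(up), sort(dn))
  })

  one_direction <- function(d_i, label) {
    rp <- rp_obs[[d_i]]
    cnt <- findInterval(log(rp) + 1e-12, null_log_rp[[d_i]])
    p <- (cnt + 1) / (n_perm * G + 1)
    pfp <- p * G / rank(p, ties.method = "max")
    ord <- order(p)
    pfp[ord] <- cummax(pfp[ord])        # enforce monotone q in p
    data.frame(id = ids, direction = label, RP = rp, p = p,
               pfp_q = pmin(1, pfp),
               bh_q = stats::p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_direction(1, "up_in_A"), one_direction(2, "up_in_B"))
  rownames(out) <- NULL
  out
}

#' Select significant items from rank-product results
#'
#' Takes the union of both directions at `q < q_threshold`, keeping the
#' direction labels.
#'
#' @param results output of [rank_product()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param q_column which q to threshold: `"pfp_q"` (rank-product native,
#'   default) or `"bh_q"`.
#' @return data.frame of significant rows (`id`, `direction`, statistics);
#'   the de-duplicated id vector is in attribute `ids`.
#' @export
identify_significant <- function(results, q_threshold = 0.05,
                                 q_column = c("pfp_q", "bh_q")) {
  q_column <- match.arg(q_column)
  sig <- results[results[[q_column]] < q_threshold, , drop = FALSE]
  attr(sig, "ids") <- unique(sig$id)
  sig
}

#' Overlap of differentially expressed genes and differential-growth strains
#'
#' @param degs character vector of DEG ids.
#' @param dggs character vector of DGG ids.
#' @param universe_deg,universe_dgg the gene universes the two selections
#'   were computed on; they must share genes.
#' @param features optional data.frame keyed by `gene` (e.g. expression
#'   means, growth means, fitness classes) joined onto the overlap table.
#' @return list with counts `deg_only`, `dgg_only`, `both`, the id vectors,
#'   and `feature_table` for genes in either set (NULL when `features` is
#'   not given).
#' @export
deg_dgg_overlap <- function(degs, dggs, universe_deg, universe_dgg,
                            features = NULL) {
  if (!length(intersect(universe_deg, universe_dgg)))
    stop("DEG and DGG universes are disjoint")
  both <- intersect(degs, dggs)
  res <- list(deg_only = length(setdiff(degs, dggs)),
              dgg_only = length(setdiff(dggs, degs)),
              both = length(both),
              genes_deg_only = setdiff(degs, dggs),
              genes_dgg_only = setdiff(dggs, degs),
              genes_both = both,
              feature_table = NULL)
  if (!is.null(features)) {
    sel <- union(degs, dggs)
    ft <- features[features$gene %in% sel, , drop = FALSE]
    ft$deg <- ft$gene %in% degs
    ft$dgg <- ft$gene %in% dggs
    res$feature_table <- ft
  }
  res
}
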