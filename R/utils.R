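#' @keywords internal
"_PACKAGE"

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage seed derivation, kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(annotation = 11L, expression = 23L, growth_truth = 37L,
            plates = 53L, layout = 71L, rankprod = 89L, shuffle = 101L)
  o <- offs[[stage]]
  (as.integer(seed) * 2654435L + o * 97L) %% 2147483629L
}

#' Serpentine well index for a 96-well plate
#'
#' Maps well identifiers (`"A1"`..`"H12"`) to a 0-based serpentine reading
#' order: row A left to right (A1..A12), row B right to left (B12..B1), and
#' so on. This fixed convention orders wells for the well-location bias
#' diagnostic.
#'
#' @param well character vector of well ids, e.g. `"A1"`, `"H12"`.
#' @param n_cols number of columns per plate row (default 12).
#' @return integer vector of 0-based serpentine indices.
#' @export
#' @examples
#' serpentine_index(c("A1", "A12", "B12", "B1"))
serpentine_index <- function(well, n_cols = 12L) {
  well <- toupper(as.character(well))
  row <- match(substr(well, 1, 1), LETTERS)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  if (anyNA(row) || anyNA(col) || any(col < 1L) || any(col > n_cols))
    stop("malformed well id(s): ",
         paste(well[is.na(row) | is.na(col)], collapse = ", "))
  idx <- ifelse((row - 1L) %% 2L == 0L, col - 1L, n_cols - col)
  as.integer((row - 1L) * n_cols + idx)
}

# Spearman correlation with tie-corrected asymptotic p (cor.test wrapper
# that errors on degenerate input rather than returning NA).
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs for a Spearman correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
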