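# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named stage
#'
#' All stochastic stages draw their seed from a single root seed plus a stage
#' name, so that stages can be re-run independently yet an end-to-end run is
#' reproducible from one integer.
#'
#' @param root_seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer in [0, 2^31 - 1].
#' @export
substream_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(root_seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Spearman correlation with two-sided p, returning NA for degenerate input.
spearman_or_na <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Fraction of missing entries per row of a dosage matrix.
row_missing_frac <- function(dosage) {
  rowMeans(is.na(dosage))
}

#' Null-coalescing operator
#' @param a,b Values; `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, else `b`.
#' @export
#' @name null-coalesce
#' @rdname null-coalesce
`%||%` <- function(a, b) if (is.null(a)) b else a
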