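# EHH/iHS selection scan for fully homozygous (doubled-haploid) haplotype
# panels: extended haplotype homozygosity curves, their physical-distance
# integrals, frequency-bin standardized iHS, empirical-p classification and
# nearest-gene annotation.

#' Extended haplotype homozygosity curve from a core site
#'
#' Among the carriers of `core_allele` at `core_site`, EHH at a site `x` in
#' the chosen direction is the fraction of carrier pairs whose haplotypes
#' are identical at every site from the core through `x`:
#' `EHH(x) = sum_g C(n_g, 2) / C(n_c, 2)` over groups `g` of
#' prefix-identical carriers. `EHH(core) = 1` and the curve is
#' non-increasing. The walk stops after the first value below `ehh_cutoff`
#' (that point is kept, so the integral's last trapezoid crosses the
#' cutoff) or at the chromosome end, in which case the curve is flagged
#' edge-censored.
#'
#' @param hpanel A `haplotype_panel`.
#' @param core_site Site index (column of `hpanel$H`).
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` or `"right"` along the chromosome.
#' @param ehh_cutoff Stop threshold.
#' @return `data.frame` with `pos` and `ehh`, first row the core site;
#'   attribute `"edge_censored"` is `TRUE` when the chromosome ended before
#'   the cutoff was reached.
#' @export
ehh <- function(hpanel, core_site, core_allele, direction = c("right", "left"),
                ehh_cutoff = 0.05) {
  stopifnot(inherits(hpanel, "haplotype_panel"))
  direction <- match.arg(direction)
  H <- hpanel$H
  carriers <- which(H[, core_site] == core_allele)
  nc <- length(carriers)
  if (nc < 2L) stop("fewer than 2 carriers of the core allele")
  chrom <- hpanel$sites$chrom
  on_chr <- which(chrom == chrom[core_site])
  path <- if (direction == "right") on_chr[on_chr > core_site]
          else rev(on_chr[on_chr < core_site])
  denom <- choose(nc, 2)
  g <- rep(1L, nc)
  pos <- hpanel$sites$pos[core_site]
  vals <- 1
  censored <- TRUE
  for (x in path) {
    g <- as.integer(factor(paste(g, H[carriers, x])))
    e <- sum(choose(tabulate(g), 2)) / denom
    pos <- c(pos, hpanel$sites$pos[x])
    vals <- c(vals, e)
    if (e < ehh_cutoff) { censored <- FALSE; break }
  }
  structure(data.frame(pos = pos, ehh = vals),
            edge_censored = censored && vals[length(vals)] >= ehh_cutoff)
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Trapezoidal integral of an EHH curve over physical distance in bp.
#' Inter-site gaps wider than `max_gap` contribute a capped width, so
#' sparse regions cannot dominate the integral.
#'
#' @param ehh_curve `data.frame` from [ehh()] (`pos`, `ehh`).
#' @param max_gap Maximum bp width any single trapezoid may contribute.
#' @return Integral in bp x EHH units (0 for a single-point curve).
#' @export
ihh <- function(ehh_curve, max_gap = 200000) {
  n <- nrow(ehh_curve)
  if (n < 2L) return(0)
  w <- pmin(abs(diff(ehh_curve$pos)), max_gap)
  sum(w * (ehh_curve$ehh[-n] + ehh_curve$ehh[-1L]) / 2)
}

#' iHS scan over a DH haplotype panel
#'
#' Per retained site (derived frequency within `[maf_min, 1 - maf_min]` and
#' at least two carriers of each allele), both-direction iHH is computed for
#' the derived and ancestral cores, `ihs_raw = ln(iHH_A / iHH_D)`, and raw
#' scores are standardized to z-scores within `n_bins` equal-width
#' derived-frequency bins. Sites whose EHH walk hit a chromosome end before
#' the cutoff are flagged `edge_censored` and excluded from standardization
#' unless `include_edge = TRUE`.
#'
#' @param hpanel A `haplotype_panel` (derived-coded).
#' @param maf_min Minimum minor (derived) frequency.
#' @param ehh_cutoff EHH stop threshold.
#' @param max_gap Gap cap in bp for the integrals.
#' @param n_bins Number of equal-width frequency bins for standardization.
#' @param include_edge Keep edge-censored sites in the standardization.
#' @return `data.frame` of class `ihs_result`: `chrom`, `pos`, `daf`,
#'   `ihh_d`, `ihh_a`, `ihs_raw`, `ihs_std`, `edge_censored` (plus
#'   `emp_p`/`significant` after [empirical_classify()]).
#' @export
ihs_scan <- function(hpanel, maf_min = 0.05, ehh_cutoff = 0.05,
                     max_gap = 200000, n_bins = 100, include_edge = FALSE) {
  stopifnot(inherits(hpanel, "haplotype_panel"))
  daf <- colMeans(hpanel$H)
  usable <- which(daf >= maf_min & daf <= 1 - maf_min)
  res <- lapply(usable, function(s) {
    out <- data.frame(site = s, chrom = hpanel$sites$chrom[s],
                      pos = hpanel$sites$pos[s], daf = daf[s],
                      ihh_d = NA_real_, ihh_a = NA_real_,
                      ihs_raw = NA_real_, edge_censored = FALSE,
                      stringsAsFactors = FALSE)
    curves <- lapply(c(1L, 0L), function(al) {
      lapply(c("left", "right"), function(dr) {
        ehh(hpanel, s, al, dr, ehh_cutoff)
      })
    })
    cens <- any(vapply(unlist(curves, recursive = FALSE),
                       function(cv) isTRUE(attr(cv, "edge_censored")),
                       logical(1)))
    ihh_d <- sum(vapply(curves[[1L]], ihh, numeric(1), max_gap = max_gap))
    ihh_a <- sum(vapply(curves[[2L]], ihh, numeric(1), max_gap = max_gap))
    out$ihh_d <- ihh_d; out$ihh_a <- ihh_a; out$edge_censored <- cens
    if (ihh_d > 0 && ihh_a > 0) out$ihs_raw <- log(ihh_a / ihh_d)
    out
  })
  res <- do.call(rbind, res)
  # frequency-bin standardization
  res$ihs_std <- NA_real_
  use <- !is.na(res$ihs_raw) & (include_edge | !res$edge_censored)
  bins <- cut(res$daf, breaks = seq(0, 1, length.out = n_bins + 1),
              include.lowest = TRUE)
  thin <- character(0)
  for (b in levels(droplevels(bins[use]))) {
    i <- which(use & bins == b)
    if (length(i) < 2L || stats::sd(res$ihs_raw[i]) == 0) {
      thin <- c(thin, b)
      next
    }
    res$ihs_std[i] <- (res$ihs_raw[i] - mean(res$ihs_raw[i])) /
      stats::sd(res$ihs_raw[i])
  }
  if (length(thin)) {
    warning(length(thin), " frequency bin(s) with < 2 usable sites; ",
            "their sites have missing standardized iHS")
  }
  class(res) <- c("ihs_result", "data.frame")
  res
}

#' Classify sites by empirical p-value on |iHS|
#'
#' The empirical p of a site is its rank of `|ihs_std|` (descending, rank 1
#' = most extreme, average rank on ties) divided by the number of sites
#' with a defined score. A site is significant when `emp_p < alpha` AND
#' `|ihs_std| > z_min` (dual-threshold rule).
#'
#' @param ihs_results `ihs_result` from [ihs_scan()].
#' @param alpha Empirical-p threshold.
#' @param z_min Minimum absolute standardized iHS.
#' @return The input with `emp_p` and `significant` columns filled.
#' @export
empirical_classify <- function(ihs_results, alpha = 0.05, z_min = 2) {
  ok <- !is.na(ihs_results$ihs_std)
  if (!any(ok)) stop("no site with a defined standardized iHS")
  a <- abs(ihs_results$ihs_std[ok])
  r <- rank(-a, ties.method = "average")
  ihs_results$emp_p <- NA_real_
  ihs_results$emp_p[ok] <- r / sum(ok)
  ihs_results$significant <- !is.na(ihs_results$emp_p) &
    ihs_results$emp_p < alpha & abs(ihs_results$ihs_std) > z_min
  ihs_results
}

#' Nearest gene for each site
#'
#' Closest gene interval by bp distance (0 when the site lies inside a
#' gene); ties are broken toward the upstream (lower-coordinate) gene.
#' The reported distance is signed as `pos - nearest gene edge`: positive
#' when the gene lies upstream (left) of the site, negative when
#' downstream. Sites on chromosomes absent from the gene set are annotated
#' `unplaced`.
#'
#' @param sites `data.frame` with `chrom`, `pos`.
#' @param genes `data.frame` from [read_genes_bed()] (1-based closed
#'   `start`/`end`, `gene`).
#' @return `data.frame`: `chrom`, `pos`, `gene`, `distance`, `side`
#'   (`inside`, `upstream`, `downstream` or `unplaced`).
#' @export
nearest_gene <- function(sites, genes) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    gene = NA_character_, distance = NA_integer_,
                    side = "unplaced", stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    gi <- gi[order(genes$start[gi])]
    si <- which(sites$chrom == ch)
    # bp distance of every site on this chromosome to every gene (0 inside)
    dmat <- vapply(gi, function(g) {
      pmax(0, pmax(as.numeric(genes$start[g]) - sites$pos[si],
                   sites$pos[si] - as.numeric(genes$end[g])))
    }, numeric(length(si)))
    dmat <- matrix(dmat, nrow = length(si))
    best <- apply(dmat, 1L, which.min)  # first minimum = lowest-coordinate gene
    for (k in seq_along(si)) {
      q <- si[k]; g <- gi[best[k]]; p <- sites$pos[q]
      if (p >= genes$start[g] && p <= genes$end[g]) {
        out$distance[q] <- 0L; out$side[q] <- "inside"
      } else if (p > genes$end[g]) {
        out$distance[q] <- p - genes$end[g]; out$side[q] <- "upstream"
      } else {
        out$distance[q] <- p - genes$start[g]; out$side[q] <- "downstream"
      }
      out$gene[q] <- genes$gene[g]
    }
  }
  out
}
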