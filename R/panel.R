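#' Genotype panel: samples x sites dosage matrix with metadata
#'
#' The central container of the pipeline. Dosages count copies of the ALT
#' allele as read from a VCF, or of the derived allele after
#' [polarize_to_ancestral()]. Missing calls are `NA`.
#'
#' @param dosage Integer matrix, samples x sites, entries in \{0, 1, 2, NA\}.
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `ancestral` (base or `NA` when unknown), `quality_class`
#'   (array quality string or `NA`). Extra columns are kept.
#' @param sample_ids Character vector, one per dosage row.
#' @param pop_of_sample Named character vector mapping sample id to
#'   population label.
#' @param polarized Logical; `TRUE` once dosages count derived alleles.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, sites, sample_ids, pop_of_sample,
                           polarized = FALSE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == nrow(sites))
  need <- c("chrom", "pos", "ref", "alt", "ancestral", "quality_class")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  sites$pos <- as.integer(sites$pos)
  bad <- setdiff(unique(dosage[!is.na(dosage)]), 0:2)
  if (length(bad)) stop("dosage entries outside {0,1,2,NA}: ", paste(bad, collapse = ","))
  unmapped <- setdiff(sample_ids, names(pop_of_sample))
  if (length(unmapped)) {
    stop("samples absent from the population map: ", paste(unmapped, collapse = ", "))
  }
  # positions strictly increasing within each chromosome
  by_chr <- split(sites$pos, sites$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("site positions must be strictly increasing within each chromosome")
  }
  dimnames(dosage) <- list(sample_ids, NULL)
  rownames(sites) <- NULL
  structure(list(
    sample_ids = as.character(sample_ids),
    pop_of_sample = pop_of_sample[sample_ids],
    sites = as.data.frame(sites),
    dosage = dosage,
    polarized = isTRUE(polarized)
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d sites (%s-coded)\n",
              length(x$sample_ids), nrow(x$sites),
              if (x$polarized) "derived" else "alt"))
  cat(sprintf("  populations: %d; chromosomes: %d; missing calls: %.3f%%\n",
              length(unique(x$pop_of_sample)),
              length(unique(x$sites$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
summary.genotype_panel <- function(object, ...) {
  pops <- table(object$pop_of_sample)
  res <- list(
    n_samples = length(object$sample_ids),
    n_sites = nrow(object$sites),
    n_pops = length(pops),
    samples_per_pop = pops,
    missing_frac = mean(is.na(object$dosage)),
    polarized = object$polarized
  )
  class(res) <- "summary.genotype_panel"
  res
}

#' @export
print.summary.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples, %d sites, %d populations\n",
              x$n_samples, x$n_sites, x$n_pops))
  cat(sprintf("  overall missingness %.4f; %s-coded\n", x$missing_frac,
              if (x$polarized) "derived" else "alt"))
  invisible(x)
}

#' Subset a genotype panel by sites and/or samples
#'
#' @param panel A `genotype_panel`.
#' @param sites Integer or logical index over sites (optional).
#' @param samples Character sample ids or index over samples (optional).
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(sites)) seq_len(nrow(panel$sites)) else sites
  sa <- if (is.null(samples)) seq_along(panel$sample_ids) else samples
  if (is.character(sa)) sa <- match(sa, panel$sample_ids)
  genotype_panel(panel$dosage[sa, si, drop = FALSE],
                 panel$sites[si, , drop = FALSE],
                 panel$sample_ids[sa],
                 panel$pop_of_sample,
                 polarized = panel$polarized)
}

#' Samples belonging to one population
#' @param panel A `genotype_panel`.
#' @param population Population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(panel, population) {
  ids <- panel$sample_ids[panel$pop_of_sample == population]
  if (!length(ids)) stop("population not in panel: ", population)
  ids
}

#' Haplotype panel for doubled-haploid (DH) lines
#'
#' DH lines are fully homozygous, so each line's genome is one naturally
#' phased haplotype: a binary vector over sites (1 = derived allele).
#'
#' @param H Binary matrix, lines x sites.
#' @param sites `data.frame` with `chrom` and 1-based `pos`, strictly
#'   increasing within chromosome.
#' @param line_ids Character ids, one per row of `H`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, sites, line_ids = rownames(H)) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(H)))
  stopifnot(ncol(H) == nrow(sites), length(line_ids) == nrow(H))
  if (any(!H %in% c(0L, 1L))) {
    stop("haplotype matrix must be binary (DH lines carry no heterozygotes)")
  }
  by_chr <- split(sites$pos, sites$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("site positions must be strictly increasing within each chromosome")
  }
  rownames(H) <- line_ids
  structure(list(line_ids = as.character(line_ids),
                 sites = as.data.frame(sites), H = H),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d DH lines x %d sites, mean derived freq %.3f\n",
              nrow(x$H), ncol(x$H), mean(colMeans(x$H))))
  invisible(x)
}

#' Convert a polarized genotype panel of DH individuals to haplotypes
#'
#' DH genotypes are homozygous, so dosages are \{0, 2\}; they collapse to a
#' single haplotype per line. Any heterozygous call is rejected.
#'
#' @param panel Polarized `genotype_panel` restricted to one DH population.
#' @return A `haplotype_panel`.
#' @export
as_haplotype_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!panel$polarized) stop("panel must be polarized to the ancestral allele first")
  d <- panel$dosage
  if (any(d == 1L, na.rm = TRUE)) {
    n_het <- sum(d == 1L, na.rm = TRUE)
    stop("panel contains ", n_het, " heterozygous call(s); not a DH panel")
  }
  if (anyNA(d)) stop("DH haplotype conversion requires complete genotypes")
  haplotype_panel(d / 2L, panel$sites, panel$sample_ids)
}
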