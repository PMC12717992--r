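# Readers and writers for the pipeline's external formats: VCF genotypes,
# sample->population maps, coordinates, GERP tracks, bioclim tables, gene
# intervals (BED) and fourfold-degenerate site lists. All tabular formats are
# TSV with a header line.

#' Read a VCF plus population map into a genotype panel
#'
#' Dosages are coded on the ALT allele (0/1/2, `NA` for `./.`); site order is
#' preserved. The ancestral allele is taken from an `AA` INFO key when
#' present, the array quality class from a `QC` INFO key. Multi-allelic
#' records are kept but flagged (`multiallelic` site column) for
#' [filter_sites()]; they are never silently split.
#'
#' @param vcf_path Path to a VCF (v4.x, GT required; plain or bgzipped).
#' @param popmap_path Path to a TSV with columns `sample`, `population`.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  unmapped <- setdiff(samples, popmap$sample)
  if (length(unmapped)) {
    stop("VCF sample(s) absent from the population map: ",
         paste(unmapped, collapse = ", "))
  }
  aa <- suppressWarnings(vcfR::extract.info(v, element = "AA"))
  qc <- suppressWarnings(vcfR::extract.info(v, element = "QC"))
  multi <- grepl(",", fix$ALT, fixed = TRUE)

  dosage <- gt_to_dosage(gt)  # sites x samples
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    ancestral = if (all(is.na(aa))) NA_character_ else aa,
    quality_class = if (all(is.na(qc))) NA_character_ else qc,
    multiallelic = multi,
    stringsAsFactors = FALSE
  )
  pops <- stats::setNames(popmap$population, popmap$sample)
  genotype_panel(t(dosage), sites, samples, pops, polarized = FALSE)
}

# GT strings -> dosage. Accepts "/" or "|" separators; any allele index > 1
# (multi-allelic secondary alleles) yields NA so flagged records carry no
# fabricated biallelic dosage.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  d[g %in% c("0/0")] <- 0L
  d[g %in% c("0/1", "1/0")] <- 1L
  d[g %in% c("1/1")] <- 2L
  d
}

#' Write a genotype panel as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with GT genotypes and `AA`/`QC` INFO keys where
#' known. Round-trips exactly through [read_genotypes()].
#'
#' @param panel A `genotype_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=QC,Number=1,Type=String,Description=\"Array quality class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  info <- vapply(seq_len(nrow(s)), function(i) {
    parts <- character(0)
    if (!is.na(s$ancestral[i])) parts <- c(parts, paste0("AA=", s$ancestral[i]))
    if (!is.na(s$quality_class[i])) parts <- c(parts, paste0("QC=", s$quality_class[i]))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, character(1))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(s), ncol = length(panel$sample_ids))
  d <- t(panel$dosage)  # sites x samples
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#' @param path TSV with columns `sample`, `population`.
#' @return `data.frame` with those columns.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population") %in% names(pm)))
  dup <- pm$sample[duplicated(pm$sample)]
  if (length(dup)) stop("duplicated sample(s) in popmap: ", paste(unique(dup), collapse = ", "))
  pm
}

#' Read population coordinates (and optional cluster labels)
#' @param path TSV with columns `population`, `latitude`, `longitude` and
#'   optionally `cluster`.
#' @return `data.frame`; invalid coordinates raise an error.
#' @export
read_coords <- function(path) {
  co <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("population", "latitude", "longitude") %in% names(co)))
  if (anyDuplicated(co$population)) stop("duplicated population in coordinates file")
  if (any(abs(co$latitude) > 90) || any(abs(co$longitude) > 180)) {
    stop("coordinates outside valid decimal-degree ranges")
  }
  co
}

#' Read a per-site GERP score track
#' @param path TSV with columns `chrom`, `pos` (1-based), `score`.
#' @return `data.frame` with unique finite-scored sites.
#' @export
read_gerp <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "score") %in% names(g)))
  if (anyDuplicated(g[c("chrom", "pos")])) stop("duplicate (chrom,pos) in GERP track")
  if (any(!is.finite(g$score))) stop("non-finite GERP score(s)")
  g
}

#' Read a per-population bioclimatic table
#' @param path TSV with columns `population`, `bio1`..`bio19` and optionally
#'   `latitude`, `longitude`.
#' @return `data.frame`.
#' @export
read_bioclim <- function(path) {
  b <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  vars <- paste0("bio", 1:19)
  miss <- setdiff(vars, names(b))
  if (length(miss)) stop("bioclim table missing variable(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(b$population)) stop("duplicated population in bioclim table")
  b
}

#' Read gene intervals from BED
#'
#' BED is half-open 0-based; intervals are converted to closed 1-based
#' coordinates on read.
#'
#' @param path BED file (chrom, start, end and optionally name).
#' @return `data.frame` with `chrom`, `start`, `end` (1-based closed), `gene`.
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least chrom/start/end")
  genes <- data.frame(
    chrom = bed[[1L]],
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]]),
    gene = if (ncol(bed) >= 4L) bed[[4L]] else paste0("gene", seq_len(nrow(bed))),
    stringsAsFactors = FALSE
  )
  if (any(genes$end < genes$start)) stop("malformed BED interval (end < start)")
  genes
}

#' Read a fourfold-degenerate (near-neutral) site list
#' @param path TSV with columns `chrom`, `pos`.
#' @return `data.frame`.
#' @export
read_fourfold <- function(path) {
  ff <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(ff)))
  ff
}

# All pipeline TSV outputs go through one writer: tab-separated, header line,
# no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
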