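# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Small deterministic genotype panel. `dosage` is samples x sites.
toy_panel <- function(dosage, chrom = NULL, pos = NULL, ref = NULL,
                      alt = NULL, ancestral = NULL, quality = NULL,
                      pops = NULL, polarized = FALSE) {
  dosage <- as.matrix(dosage)
  ns <- ncol(dosage)
  n <- nrow(dosage)
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", ns),
    pos = pos %||% seq(1000, by = 1000, length.out = ns),
    ref = ref %||% rep("A", ns),
    alt = alt %||% rep("G", ns),
    ancestral = ancestral %||% rep("A", ns),
    quality_class = quality %||% rep("PolyHighResolution", ns),
    stringsAsFactors = FALSE
  )
  ids <- sprintf("s%02d", seq_len(n))
  pops <- pops %||% rep("P1", n)
  genotype_panel(dosage, sites, ids, stats::setNames(pops, ids),
                 polarized = polarized)
}

# Random panel with reproducible dosages and optional missingness.
random_panel <- function(seed, n = 6, ns = 30, miss = 0, pops = NULL) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * ns, TRUE), n, ns)
  if (miss > 0) d[matrix(runif(n * ns) < miss, n, ns)] <- NA
  anc <- ifelse(runif(ns) < 0.5, "A", "G")  # mix of ref- and alt-ancestral
  toy_panel(d, ancestral = anc, pops = pops)
}

# Small, fast simulation config for recovery tests.
quick_sim_config <- function(seed, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_pops = 10, n_per_pop = 10, n_sites = 500,
    generations_per_edge = 15, n_elite_pops = 0, missing_rate = 0,
    junk_quality_frac = 0
  ), list(...))
  do.call(sim_config, args)
}

# Random haplotype panel for EHH oracles.
random_hpanel <- function(seed, n_lines = 6, ns = 15) {
  set.seed(seed)
  H <- matrix(rbinom(n_lines * ns, 1, 0.5), n_lines, ns)
  haplotype_panel(H, data.frame(chrom = "chr1",
                                pos = seq(1000, by = 500, length.out = ns)))
}

# Brute-force EHH oracle: for each site outward from the core, count carrier
# pairs identical at every site from the core through it.
ehh_oracle <- function(H, sites, core, allele, direction) {
  carriers <- which(H[, core] == allele)
  nc <- length(carriers)
  on_chr <- which(sites$chrom == sites$chrom[core])
  path <- if (direction == "right") on_chr[on_chr > core]
          else rev(on_chr[on_chr < core])
  pos <- sites$pos[core]; vals <- 1
  for (k in seq_along(path)) {
    span <- if (direction == "right") core:path[k] else path[k]:core
    ident <- 0
    for (a in seq_len(nc - 1)) for (b in seq((a + 1), nc)) {
      if (all(H[carriers[a], span] == H[carriers[b], span])) ident <- ident + 1
    }
    pos <- c(pos, sites$pos[path[k]])
    vals <- c(vals, ident / choose(nc, 2))
  }
  data.frame(pos = pos, ehh = vals)
}
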