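# Config-driven orchestration: filter -> diversity -> differentiation ->
# sweep scan -> RDA -> load, with stage logging, substream seeding, TSV
# outputs and a machine-readable JSON run report.

#' Default pipeline parameters
#'
#' Stage parameters used when a run config does not override them. Quality
#' whitelist and block size follow array-data conventions; LD pruning
#' windows are counted in variants; iHS defaults follow common scan-tool
#' settings.
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(
    quality_whitelist = c("PolyHighResolution", "MonoHighResolution",
                          "NoMinorHom"),
    max_site_missing = 0.2,
    drop_monomorphic = TRUE,
    ld = list(window = 500, step = 200, n_iter = 5, r2_max = 0.1,
              unit = "variants", enabled = FALSE),
    fst_block_size = 100000,
    ihs = list(maf_min = 0.05, ehh_cutoff = 0.05, max_gap = 200000,
               n_bins = 100, alpha = 0.05, z_min = 2),
    n_dh_lines = 500,
    rda = list(n_perm = 999, n_pcs = 2, alpha = 0.05, max_sites = 2000),
    load = list(high_threshold = 5, missing_quantile = 0.95),
    entry_south = NULL, entry_north = NULL
  )
}

# Merge user params over defaults (one level of nesting).
merge_params <- function(user) {
  p <- default_params()
  for (nm in names(user)) {
    p[[nm]] <- if (is.list(p[[nm]]) && is.list(user[[nm]])) {
      utils::modifyList(p[[nm]], user[[nm]])
    } else user[[nm]]
  }
  p
}

#' Validate a run configuration and its input files
#'
#' Cheap cross-file consistency checks (VCF samples vs popmap, populations
#' vs coordinates/bioclim, GERP coverage, duplicate samples) run before any
#' heavy computation.
#'
#' @param config Run config list (see [run_pipeline()]).
#' @return Character vector of problems (empty when consistent).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(x) problems <<- c(problems, x)
  if (is.null(config$simulate) && is.null(config$inputs)) {
    add("config needs either a 'simulate' block or an 'inputs' block")
    return(problems)
  }
  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    add("config has both 'simulate' and 'inputs'; choose one")
  }
  if (is.null(config$seed)) add("seed is mandatory")
  inp <- config$inputs
  if (is.null(inp)) return(problems)
  for (f in c("vcf", "popmap", "coords")) {
    if (is.null(inp[[f]])) add(paste0("missing required input path: ", f))
    else if (!file.exists(inp[[f]])) add(paste0(f, " file not found: ", inp[[f]]))
  }
  if (length(problems)) return(problems)
  pm <- tryCatch(read_popmap(inp$popmap), error = function(e) {
    add(conditionMessage(e)); NULL
  })
  co <- tryCatch(read_coords(inp$coords), error = function(e) {
    add(conditionMessage(e)); NULL
  })
  # VCF sample names from the header line only
  con <- file(inp$vcf, "r"); on.exit(close(con))
  hdr <- NULL
  repeat {
    l <- readLines(con, 1L)
    if (!length(l)) break
    if (startsWith(l, "#CHROM")) { hdr <- l; break }
  }
  if (is.null(hdr)) {
    add("VCF has no #CHROM header line")
  } else if (!is.null(pm)) {
    vs <- strsplit(hdr, "\t")[[1]][-(1:9)]
    missing_pm <- setdiff(vs, pm$sample)
    if (length(missing_pm)) {
      add(paste0("VCF sample(s) absent from popmap: ",
                 paste(utils::head(missing_pm, 5), collapse = ", ")))
    }
  }
  if (!is.null(pm) && !is.null(co)) {
    missing_co <- setdiff(unique(pm$population), co$population)
    if (length(missing_co)) {
      add(paste0("population(s) without coordinates: ",
                 paste(missing_co, collapse = ", ")))
    }
  }
  if (!is.null(inp$bioclim) && file.exists(inp$bioclim) && !is.null(pm)) {
    bc <- tryCatch(read_bioclim(inp$bioclim), error = function(e) {
      add(conditionMessage(e)); NULL
    })
    if (!is.null(bc)) {
      missing_bc <- setdiff(unique(pm$population), bc$population)
      if (length(missing_bc)) {
        add(paste0("population(s) without bioclim values: ",
                   paste(missing_bc, collapse = ", ")))
      }
    }
  }
  problems
}

#' Read a YAML run config
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Stages execute in order: filter, diversity, differentiation, sweep scan
#' (per DH panel), RDA, load. Each enabled stage writes TSV outputs under
#' `out_dir` and appends parameters and key numbers to the JSON run report.
#' A failing stage halts its dependents; completed outputs persist.
#'
#' @param config List with `seed`, `out_dir`, optional `params` (see
#'   [default_params()]), optional `stages` (character subset of
#'   `c("diversity","differentiation","sweep","rda","load")`), and either
#'   `simulate` (arguments to [sim_config()]) or `inputs` (paths: `vcf`,
#'   `popmap`, `coords`, and optionally `gerp`, `bioclim`, `genes`,
#'   `fourfold`, `groups`).
#' @return List of class `run_report` with per-stage results; also written
#'   to `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  seed <- config$seed
  out_dir <- config$out_dir %||% tempfile("landrace_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- merge_params(config$params %||% list())
  stages <- config$stages %||% c("diversity", "differentiation", "sweep",
                                 "rda", "load")
  report <- list(seed = seed, params = params, stages = stages,
                 package_version = as.character(utils::packageVersion("landracepopgen")),
                 results = list())
  sim <- NULL

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, utils::modifyList(config$simulate,
                                                 list(seed = seed)))
    sim <- simulate_expansion(cfg)
    files <- write_sim_bundle(sim, file.path(out_dir, "sim"))
    inputs <- as.list(files)
    if (is.null(params$entry_south)) params$entry_south <- "S01"
    if (is.null(params$entry_north)) params$entry_north <- "N01"
  } else {
    inputs <- config$inputs
  }
  report$input_md5 <- vapply(inputs[vapply(inputs, function(f)
    is.character(f) && file.exists(f), logical(1))],
    function(f) unname(tools::md5sum(f)), character(1))

  panel <- read_genotypes(inputs$vcf, inputs$popmap)
  popmap <- read_coords(inputs$coords)
  gerp <- if (!is.null(inputs$gerp)) read_gerp(inputs$gerp) else NULL
  bioclim <- if (!is.null(inputs$bioclim)) read_bioclim(inputs$bioclim) else NULL
  genes <- if (!is.null(inputs$genes)) read_genes_bed(inputs$genes) else NULL
  fourfold <- if (!is.null(inputs$fourfold)) read_fourfold(inputs$fourfold) else NULL
  groups <- if (!is.null(inputs$groups)) {
    gm <- utils::read.table(inputs$groups, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stats::setNames(gm$group, gm$sample)
  } else NULL
  cluster_of <- if ("cluster" %in% names(popmap)) {
    stats::setNames(popmap$cluster, popmap$population)
  } else NULL

  # --- filter (always runs) ----------------------------------------------
  panel <- filter_sites(panel,
                        quality_whitelist = params$quality_whitelist,
                        max_site_missing = params$max_site_missing,
                        drop_monomorphic = params$drop_monomorphic)
  report$results$filter <- list(
    n_sites = nrow(panel$sites),
    attrition = as.list(attr(panel, "attrition")))
  if (isTRUE(params$ld$enabled)) {
    panel <- ld_prune(panel, params$ld$window, params$ld$step,
                      params$ld$n_iter, params$ld$r2_max, params$ld$unit)
    report$results$filter$n_sites_ld_pruned <- nrow(panel$sites)
  }
  landrace_pops <- if (!is.null(cluster_of)) {
    names(cluster_of)[cluster_of != "elite"]
  } else unique(panel$pop_of_sample)
  landrace_panel <- subset_panel(
    panel, samples = which(panel$pop_of_sample %in% landrace_pops))

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    message("== stage: ", name, " ==")
    res <- tryCatch(fun(), error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    report$results[[name]] <<- res
    invisible(res)
  }

  # --- diversity ----------------------------------------------------------
  run_stage("diversity", function() {
    stopifnot(!is.null(params$entry_south), !is.null(params$entry_north))
    dt <- diversity_table(landrace_panel,
                          popmap[popmap$population %in% landrace_pops, ],
                          params$entry_south, params$entry_north)
    write_tsv(dt, file.path(out_dir, "diversity.tsv"))
    fi <- inbreeding_f(landrace_panel)
    write_tsv(fi, file.path(out_dir, "inbreeding.tsv"))
    hx <- stats::setNames(dt$mean_hexp, dt$population)
    gs <- gradient_correlation(hx, params$entry_south, popmap)
    gn <- gradient_correlation(hx, params$entry_north, popmap)
    list(mean_hexp = mean(dt$mean_hexp), median_hexp = stats::median(dt$mean_hexp),
         hexp_vs_south = gs[c("rho", "p")], hexp_vs_north = gn[c("rho", "p")],
         median_inbreeding = stats::median(fi$F, na.rm = TRUE))
  })

  # --- differentiation ----------------------------------------------------
  run_stage("differentiation", function() {
    fst <- pairwise_fst(landrace_panel, block_size = params$fst_block_size)
    geo <- geo_distance_matrix(popmap[match(fst$populations, popmap$population), ])
    long <- fst$pairs
    long$geo_km <- geo[cbind(long$popA, long$popB)]
    env <- NULL
    if (!is.null(bioclim)) {
      env <- environmental_distance(
        bioclim[bioclim$population %in% fst$populations, ])
      env <- env[fst$populations, fst$populations]
      long$env_dist <- env[cbind(long$popA, long$popB)]
    }
    write_tsv(long, file.path(out_dir, "fst_pairs.tsv"))
    ibd_geo <- ibd_test(fst$fst, geo)
    res <- list(fst_mean = mean(fst$fst[upper.tri(fst$fst)]),
                fst_median = stats::median(fst$fst[upper.tri(fst$fst)]),
                ibd_geo = ibd_geo[c("rho", "p")])
    if (!is.null(env)) res$ibd_env <- ibd_test(fst$fst, env)[c("rho", "p")]
    if (!is.null(cluster_of)) {
      cc <- cluster_contrast(fst$fst, cluster_of)
      res$cluster_contrast <- cc[c("ks_statistic", "p", "median_within",
                                   "median_between")]
      res$ibd_geo_within <- ibd_test(fst$fst, geo, "within-cluster",
                                     cluster_of)[c("rho", "p")]
      res$ibd_geo_between <- ibd_test(fst$fst, geo, "between-cluster",
                                      cluster_of)[c("rho", "p")]
    }
    res
  })

  # --- sweep scan ----------------------------------------------------------
  run_stage("sweep", function() {
    panels <- list()
    if (!is.null(sim) && length(sim$truth$sweeps)) {
      for (sw in sim$truth$sweeps) {
        hp <- make_dh_panel(sim$truth$pop_freqs[sw$population, ],
                            sim$panel$sites, params$n_dh_lines, sw,
                            seed = substream_seed(seed, paste0("dh-", sw$population)))
        panels[[sw$population]] <- hp
      }
    } else if (!is.null(config$dh_populations)) {
      pol <- polarize_to_ancestral(panel)
      for (pp in config$dh_populations) {
        panels[[pp]] <- as_haplotype_panel(
          subset_panel(pol, samples = pop_samples(pol, pp)))
      }
    }
    if (!length(panels)) return(list(note = "no DH panel available"))
    out <- list()
    for (pp in names(panels)) {
      ih <- ihs_scan(panels[[pp]], params$ihs$maf_min, params$ihs$ehh_cutoff,
                     params$ihs$max_gap, params$ihs$n_bins)
      ih <- empirical_classify(ih, params$ihs$alpha, params$ihs$z_min)
      if (!is.null(genes)) {
        ng <- nearest_gene(ih[c("chrom", "pos")], genes)
        ih$nearest_gene <- ng$gene
        ih$gene_distance <- ng$distance
      }
      write_tsv(ih, file.path(out_dir, paste0("ihs_", pp, ".tsv")))
      out[[pp]] <- list(n_sites = nrow(ih),
                        n_significant = sum(ih$significant, na.rm = TRUE))
    }
    out
  })

  # --- RDA ----------------------------------------------------------------
  run_stage("rda", function() {
    if (is.null(bioclim) || is.null(fourfold)) {
      return(list(note = "bioclim or fourfold inputs absent; stage skipped"))
    }
    pcs <- neutral_pcs(landrace_panel, fourfold, params$rda$n_pcs)
    resp <- landrace_panel$dosage
    if (ncol(resp) > params$rda$max_sites) {
      set.seed(substream_seed(seed, "rda-sites"))
      resp <- resp[, sort(sample.int(ncol(resp), params$rda$max_sites)),
                   drop = FALSE]
    }
    storage.mode(resp) <- "double"
    for (j in seq_len(ncol(resp))) {
      resp[is.na(resp[, j]), j] <- mean(resp[, j], na.rm = TRUE)
    }
    pop_of <- landrace_panel$pop_of_sample
    bidx <- match(pop_of, bioclim$population)
    climate_all <- as.matrix(bioclim[bidx, paste0("bio", 1:19)])
    lat_lon <- as.matrix(popmap[match(pop_of, popmap$population),
                                c("latitude", "longitude")])
    sel <- forward_select(resp, as.data.frame(climate_all),
                          alpha = params$rda$alpha,
                          n_perm = params$rda$n_perm,
                          seed = substream_seed(seed, "rda-fwd"))
    write_tsv(sel, file.path(out_dir, "rda_forward_selection.tsv"))
    res <- list(selected = sel$variable,
                selection_table = sel)
    if (nrow(sel)) {
      vp <- variance_partition(resp, climate_all[, sel$variable, drop = FALSE],
                               pcs, lat_lon, n_perm = params$rda$n_perm,
                               seed = substream_seed(seed, "rda-vp"))
      write_tsv(vp$model_table, file.path(out_dir, "rda_models.tsv"))
      res$model_table <- vp$model_table
      res$best_model <- vp$best_model
      res$route_gradients <- lapply(sel$variable, function(v) {
        g <- route_correlation(bioclim, v, params$entry_south, popmap)
        list(variable = v, rho = g$rho, p = g$p)
      })
    }
    if (!is.null(cluster_of)) {
      ct <- cluster_bioclim_tests(
        bioclim[bioclim$population %in% landrace_pops, ],
        cluster_of[landrace_pops])
      write_tsv(ct$table, file.path(out_dir, "bioclim_cluster_tests.tsv"))
      res$n_bioclim_significant <- ct$n_significant
    }
    res
  })

  # --- load ---------------------------------------------------------------
  run_stage("load", function() {
    if (is.null(gerp)) return(list(note = "no GERP input; stage skipped"))
    pol <- polarize_to_ancestral(panel)
    ex <- exclude_high_missing(pol, params$load$missing_quantile)
    gof <- groups %||% stats::setNames(
      paste0("landrace-", cluster_of[ex$panel$pop_of_sample]),
      ex$panel$sample_ids)
    lt <- load_table(ex$panel, gerp, gof, params$load$high_threshold)
    write_tsv(lt, file.path(out_dir, "load_samples.tsv"))
    part <- partition_load(ex$panel, gerp, gof)
    write_tsv(part$groups, file.path(out_dir, "load_groups.tsv"))
    corr <- load_correlates(
      lt[lt$population %in% landrace_pops, ], popmap,
      c(south = params$entry_south, north = params$entry_north),
      bioclim, if ("rda" %in% names(report$results))
        report$results$rda$selected %||% character(0) else character(0))
    # group contrasts over all groups (elite pools included)
    corr$group_contrasts <- load_correlates(
      lt, popmap,
      c(south = params$entry_south, north = params$entry_north))$group_contrasts
    write_tsv(corr$correlations, file.path(out_dir, "load_correlations.tsv"))
    list(n_excluded = length(ex$excluded),
         missing_threshold = ex$threshold,
         mean_total_load = mean(lt$total_load),
         mean_high_del = mean(lt$high_del_count),
         correlations = corr$correlations,
         group_contrasts = corr$group_contrasts)
  })

  report$params <- params  # echo resolved parameters (incl. entry points)
  report$outputs <- list.files(out_dir, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  report$out_dir <- out_dir
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (seed ", x$seed, "), stages: ",
      paste(x$stages, collapse = ", "), "\n", sep = "")
  cat("outputs in ", x$out_dir, ":\n  ", paste(x$outputs, collapse = "\n  "),
      "\n", sep = "")
  invisible(x)
}
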