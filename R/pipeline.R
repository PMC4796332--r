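#' Build a pipeline configuration
#'
#' Either `genotypes` + `populations` paths (tabular dialect) or a
#' `synthetic` [sim_panel_spec()] must be supplied. The seed propagates to
#' every stochastic stage (synthesis, phasing restarts, MCMC, simulation).
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param genotypes,populations input paths (tabular dialect), or NULL.
#' @param synthetic a [sim_panel_spec()], or NULL.
#' @param max_sample_missing,max_snp_missing QC thresholds.
#' @param motif_loci locus ids of the core motif (NULL = panel default).
#' @param assoc_modes association codings to run.
#' @param mcmc list of [fit_selection()] settings for the selection stage
#'   (set to `NULL` to skip the stage).
#' @param network_min_count haplotype count filter for the network stage.
#' @param sim_grid list with `p0_set`, `split_set`, `sigma`, `replicates`
#'   for the simulation stage (set to `NULL` to skip).
#' @param seed master seed.
#' @return list with class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            genotypes = NULL, populations = NULL,
                            synthetic = NULL,
                            max_sample_missing = 0.20, max_snp_missing = 0.30,
                            motif_loci = NULL,
                            assoc_modes = c("additive", "dominant", "recessive"),
                            mcmc = list(pilot_runs = 3L, pilot_len = 100L,
                                        burn_in = 500L, thin = 2L,
                                        n_samples = 300L),
                            network_min_count = 1L,
                            sim_grid = list(p0_set = c(0.01, 0.05, 0.1),
                                            split_set = c(2800, 10000, 30000),
                                            sigma = 118, replicates = 20L),
                            seed = 1L) {
  if (is.null(synthetic)) {
    if (is.null(genotypes) || is.null(populations)) {
      stop("config needs either a synthetic spec or genotype + population paths")
    }
    if (!file.exists(genotypes)) stop("genotype file not found: ", genotypes)
    if (!file.exists(populations)) stop("population file not found: ", populations)
  }
  structure(list(out_dir = out_dir, genotypes = genotypes,
                 populations = populations, synthetic = synthetic,
                 max_sample_missing = max_sample_missing,
                 max_snp_missing = max_snp_missing, motif_loci = motif_loci,
                 assoc_modes = assoc_modes, mcmc = mcmc,
                 network_min_count = network_min_count, sim_grid = sim_grid,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — data (ingest or synthesis), QC, phasing,
#' core-haplotype frequencies, altitude correlation, association, selection
#' inference, network construction, forward simulation — writing every
#' intermediate artifact under `out_dir` plus a JSON manifest with artifact
#' checksums, seeds and stage wall-times. With `resume = TRUE`, stages whose
#' cached state file already exists are skipped and downstream stages reuse
#' it, so deleting one stage's state re-runs only that stage and its
#' dependents' missing pieces.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage state files.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  t_all <- proc.time()[["elapsed"]]

  stage <- function(name, artifacts, compute) {
    state_file <- file.path(config$out_dir, paste0(name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (resume && file.exists(state_file)) {
      value <- readRDS(state_file)
      cached <- TRUE
    } else {
      value <- tryCatch(compute(), error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      })
      saveRDS(value, state_file)
      cached <- FALSE
    }
    files <- file.path(config$out_dir, artifacts)
    files <- files[file.exists(files)]
    manifest$stages[[name]] <<- list(
      cached = cached,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      checksums = as.list(tools::md5sum(files)))
    value
  }

  opath <- function(f) file.path(config$out_dir, f)

  data_st <- stage("data", c("genotypes.tsv", "populations.tsv", "truth.tsv"), function() {
    if (!is.null(config$synthetic)) {
      sim <- simulate_panel(config$synthetic)
      write_genotypes(sim$panel, opath("genotypes.tsv"))
      write_populations(sim$panel$populations, opath("populations.tsv"))
      utils::write.table(sim$truth, opath("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sim
    } else {
      pops <- read_populations(config$populations)
      panel <- read_genotypes(config$genotypes, "tabular", populations = pops)
      list(panel = panel, truth = NULL)
    }
  })

  qc_st <- stage("qc", c("qc_report.txt", "qc_report.tsv"), function() {
    rep <- run_qc(data_st$panel, config$max_sample_missing, config$max_snp_missing)
    write_qc_report(rep, opath("qc_report"))
    rep
  })
  panel <- qc_st$panel

  hap_st <- stage("phase", c("haplotypes.tsv", "assignments.tsv"), function() {
    hs <- em_phase(panel, seed = derive_seed(config$seed, 2L))
    write_haplotypes(hs, opath("haplotypes.tsv"))
    utils::write.table(hs$assignments, opath("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hs
  })

  freq_st <- stage("core_freq", "core_freq.tsv", function() {
    motif <- if (is.null(config$motif_loci)) core_motif(panel$loci) else
      core_motif(panel$loci, config$motif_loci)
    ft <- pop_core_frequencies(hap_st, panel, motif)
    utils::write.table(ft, opath("core_freq.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ft
  })

  corr_st <- stage("correlate", "correlation.tsv", function() {
    ac <- altitude_correlation(freq_st)
    utils::write.table(
      data.frame(rho = ac$rho, p_value = ac$p_value, n = ac$n, method = ac$method),
      opath("correlation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    ac
  })

  assoc_st <- stage("assoc", paste0("assoc_", config$assoc_modes, ".tsv"), function() {
    res <- lapply(config$assoc_modes, function(m) {
      tab <- altitude_association(panel, m)
      utils::write.table(tab, opath(paste0("assoc_", m, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab
    })
    names(res) <- config$assoc_modes
    res
  })

  sel_st <- NULL
  if (!is.null(config$mcmc)) {
    sel_st <- stage("selection", "selection.tsv", function() {
      counts <- deme_allele_counts(panel)
      keep <- apply(counts$total > 0, 1L, all)
      if (sum(keep) < 2L) stop("fewer than 2 demes with complete allele counts")
      fit <- do.call(fit_selection, c(
        list(derived_counts = counts$derived[keep, , drop = FALSE],
             total_counts = counts$total[keep, , drop = FALSE],
             seed = derive_seed(config$seed, 3L)),
        config$mcmc))
      utils::write.table(fit$summary, opath("selection.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fit
    })
  }

  net_st <- stage("network", c("network.edges.tsv", "network.gml"), function() {
    net <- median_joining(hap_st$haplotypes, hap_st$counts,
                          min_count = config$network_min_count)
    write_network(net, opath("network"))
    net
  })

  sim_st <- NULL
  if (!is.null(config$sim_grid)) {
    sim_st <- stage("simulate", "sim_grid.tsv", function() {
      g <- config$sim_grid
      tab <- scenario_grid(p0_set = g$p0_set, split_set = g$split_set,
                           sigma = g$sigma, replicates = g$replicates,
                           seed = derive_seed(config$seed, 4L))
      utils::write.table(tab, opath("sim_grid.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      tab
    })
  }

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, panel = panel, qc = qc_st,
                 haplotypes = hap_st, core_freq = freq_st,
                 correlation = corr_st, association = assoc_st,
                 selection = sel_st, network = net_st, simulation = sim_st))
}

#' Per-population derived/total allele counts
#'
#' Collapses a genotype panel into the deme x locus count matrices consumed
#' by [fit_selection()]; missing calls are excluded from the totals.
#'
#' @param panel a `genotype_panel`.
#' @return list of matrices `derived` and `total` (populations x loci).
#' @export
deme_allele_counts <- function(panel) {
  pops <- unique(panel$samples$population)
  derived <- t(vapply(pops, function(cd) {
    sub <- panel$dosages[panel$samples$population == cd, , drop = FALSE]
    colSums(sub, na.rm = TRUE)
  }, numeric(ncol(panel$dosages))))
  total <- t(vapply(pops, function(cd) {
    sub <- panel$dosages[panel$samples$population == cd, , drop = FALSE]
    2 * colSums(!is.na(sub))
  }, numeric(ncol(panel$dosages))))
  rownames(derived) <- rownames(total) <- pops
  colnames(derived) <- colnames(total) <- panel$loci$id
  list(derived = derived, total = total)
}
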