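## Stage orchestration: simulate -> filter -> stats -> scan -> ld -> ne ->
## pca -> admixture, driven by one (YAML or list) config, with a run
## manifest hashing every output file.

pipeline_stage_order <- c("simulate", "filter", "stats", "scan", "ld", "ne",
                          "pca", "admixture")
pipeline_known_keys <- c("out_dir", "seed", "stages", "input",
                         pipeline_stage_order)

#' Validate a pipeline configuration
#'
#' @param config A named list, or path to a YAML file with the same schema:
#'   top-level `out_dir`, `seed`, `stages` (subset of
#'   simulate/filter/stats/scan/ld/ne/pca/admixture), optional `input`
#'   (`vcf`, `popmap`, `gff` paths when not simulating) and one optional
#'   parameter block per stage. Unknown keys are rejected.
#' @return The validated config list, with stages ordered canonically.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  if (is.null(config$seed)) stop("config needs seed")
  if (is.null(config$stages)) stop("config needs stages")
  bad <- setdiff(config$stages, pipeline_stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"simulate" %in% config$stages && is.null(config$input$vcf)) {
    stop("config needs input$vcf when the simulate stage is not run")
  }
  if ("scan" %in% config$stages &&
      (is.null(config$scan$pop_ref) || is.null(config$scan$pop_focal))) {
    stop("scan stage needs pop_ref and pop_focal")
  }
  if ("scan" %in% config$stages) {
    known_pops <- NULL
    if (!is.null(config$input$popmap) && file.exists(config$input$popmap)) {
      known_pops <- unique(read_population_map(config$input$popmap)$population)
    } else if ("simulate" %in% config$stages &&
               (config$simulate$generator %||% "bn") == "bn") {
      known_pops <- config$simulate$pop_labels %||%
        paste0("POP", seq_len(config$simulate$n_pops %||% 2))
    }
    if (!is.null(known_pops)) {
      bad_pop <- setdiff(c(config$scan$pop_ref, config$scan$pop_focal),
                         known_pops)
      if (length(bad_pop)) {
        stop("scan references unknown population label(s): ",
             paste(bad_pop, collapse = ", "))
      }
    }
  }
  config$stages <- pipeline_stage_order[pipeline_stage_order %in% config$stages]
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

call_with <- function(fn, fixed, params) {
  do.call(fn, c(fixed, params))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (simulate, filter, stats, scan, ld, ne, pca, admixture), writing each
#' stage's tables under `out_dir/<stage>/` and a `manifest.json` listing
#' every output file with parameters and an MD5 content hash. Reruns with
#' the same config and inputs reproduce identical manifests. A failing
#' stage halts the pipeline with the stage named; its partial output
#' directory is renamed with a `.partial` suffix and the manifest of the
#' completed stages is written to `manifest.partial.json`.
#'
#' @param config See [validate_run_config()].
#' @return The run manifest (named list, one entry per executed stage),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_root <- config$out_dir
  dir.create(out_root, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed, package_version =
                     as.character(utils::packageVersion("radsweep")),
                   stages = list())

  state <- new.env(parent = emptyenv())
  if (!is.null(config$input$vcf)) {
    v <- read_vcf(config$input$vcf)
    state$vt <- v$variants; state$gm <- v$genotypes; state$contigs <- v$contigs
  }
  if (!is.null(config$input$popmap)) {
    state$pmap <- read_population_map(config$input$popmap)
  }
  if (!is.null(config$input$gff)) {
    state$genes <- read_gff_genes(config$input$gff)
  }

  finish_manifest <- function(suffix = "") {
    path <- file.path(out_root, paste0("manifest", suffix, ".json"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }

  for (stage in config$stages) {
    sdir <- file.path(out_root, stage)
    params <- config[[stage]]
    res <- tryCatch(
      run_stage(stage, params, state, sdir, seed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (dir.exists(sdir)) {
        file.rename(sdir, paste0(sdir, ".partial"))
      }
      finish_manifest(".partial")
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(res)), call. = FALSE)
    }
    hashes <- as.list(tools::md5sum(res))
    names(hashes) <- basename(res)
    manifest$stages[[stage]] <- list(
      params = if (is.null(params)) list() else params,
      outputs = hashes)
  }
  finish_manifest()
  invisible(manifest)
}

## Execute one stage; returns the character vector of files written.
run_stage <- function(stage, params, state, sdir, seed) {
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  p <- if (is.null(params)) list() else params
  switch(stage,
    simulate = {
      generator <- p$generator %||% "bn"
      p$generator <- NULL
      if (is.null(p$seed)) p$seed <- seed
      sim <- if (generator == "bn") {
        sweeps <- p$sweep_regions
        p$sweep_regions <- NULL
        fs <- p$freq_shift %||% 0.98; p$freq_shift <- NULL
        pr <- p$pi_reduction %||% 10; p$pi_reduction <- NULL
        s <- do.call(simulate_balding_nichols, p)
        if (!is.null(sweeps)) {
          s <- plant_sweeps(s, as.data.frame(do.call(rbind, lapply(sweeps, as.data.frame))),
                            freq_shift = fs, pi_reduction = pr,
                            seed = p$seed + 1L)
        }
        s
      } else if (generator == "wf") {
        do.call(simulate_wright_fisher, p)
      } else {
        stop("unknown generator: ", generator)
      }
      files <- write_simulation(sim, sdir, gff = TRUE)
      state$vt <- sim$variants; state$gm <- sim$genotypes
      state$pmap <- sim$pmap; state$contigs <- sim$contigs
      state$genes <- read_gff_genes(files[["genes"]])
      unname(files)
    },
    filter = {
      need_state(state, c("vt", "gm"), stage)
      res <- call_with(filter_pipeline,
                       list(gm = state$gm, vt = state$vt, pmap = state$pmap),
                       p)
      state$gm <- res$genotypes; state$vt <- res$variants
      c(write_tsv(res$report, file.path(sdir, "filter_report.tsv")),
        write_vcf(state$vt, state$gm, file.path(sdir, "filtered.vcf"),
                  contigs = state$contigs))
    },
    stats = {
      need_state(state, c("vt", "gm", "pmap"), stage)
      tab <- call_with(diversity_table,
                       list(gm = state$gm, vt = state$vt, pmap = state$pmap),
                       p)
      dens <- snp_density(state$vt)
      c(write_tsv(tab, file.path(sdir, "diversity.tsv")),
        write_tsv(dens, file.path(sdir, "snp_density.tsv")))
    },
    scan = {
      need_state(state, c("vt", "gm", "pmap"), stage)
      res <- call_with(sweep_scan,
                       list(gm = state$gm, vt = state$vt, pmap = state$pmap,
                            genes = state$genes),
                       p)
      thr <- data.frame(z_threshold = res$z_threshold,
                        ratio_threshold = res$ratio_threshold)
      c(write_tsv(res$windows, file.path(sdir, "windows.tsv")),
        write_tsv(res$regions, file.path(sdir, "regions.tsv")),
        write_tsv(thr, file.path(sdir, "thresholds.tsv")))
    },
    ld = {
      need_state(state, c("vt", "gm"), stage)
      if (is.null(p$seed)) p$seed <- seed
      pairs <- call_with(ld_pairs, list(gm = state$gm, vt = state$vt), p)
      bins <- ld_decay_bins(pairs, n = nrow(state$gm$dosages))
      state$ld_bins <- bins
      c(write_tsv(bins, file.path(sdir, "ld_decay.tsv")))
    },
    ne = {
      need_state(state, c("ld_bins"), stage)
      ne <- call_with(ne_from_ld,
                      list(bins = state$ld_bins,
                           n = nrow(state$gm$dosages)), p)
      c(write_tsv(ne, file.path(sdir, "ne.tsv")))
    },
    pca = {
      need_state(state, c("gm"), stage)
      res <- call_with(pca_genotypes, list(gm = state$gm), p)
      coords <- data.frame(sample = rownames(res$coords), res$coords)
      c(write_tsv(coords, file.path(sdir, "pca_coords.tsv")),
        write_tsv(data.frame(component = seq_along(res$eigenvalues),
                             eigenvalue = res$eigenvalues),
                  file.path(sdir, "pca_eigenvalues.tsv")))
    },
    admixture = {
      need_state(state, c("gm"), stage)
      if (is.null(p$seed)) p$seed <- seed
      if (!is.null(p$k_range)) p$k_range <- as.integer(unlist(p$k_range))
      res <- call_with(choose_k, list(gm = state$gm), p)
      best <- res$fits[[as.character(res$best_k)]]
      q <- data.frame(sample = rownames(best$Q), best$Q)
      names(q) <- c("sample", paste0("q", seq_len(best$K)))
      c(write_tsv(res$table, file.path(sdir, "cv_table.tsv")),
        write_tsv(q, file.path(sdir, "Q_best.tsv")))
    },
    stop("unknown stage: ", stage)
  )
}

need_state <- function(state, what, stage) {
  miss <- what[!vapply(what, function(w) !is.null(state[[w]]), logical(1))]
  if (length(miss)) {
    stop(sprintf("stage '%s' needs %s from an earlier stage or input",
                 stage, paste(miss, collapse = ", ")))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
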