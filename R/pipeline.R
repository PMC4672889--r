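# Staged pipeline driver: validate config -> (simulate | read) ->
# normalize -> filter -> occupancy -> tests -> targets -> DE -> motif scan
# -> result TSVs + JSON manifest. Same config + seed => byte-identical
# outputs; nothing written depends on wall clock or locale.

#' Build and validate a pipeline configuration
#'
#' A configuration is a list (or a YAML file containing one) with exactly
#' one of `simulation` (arguments for [sim_config()], plus an optional
#' `utr` block of [generate_utr_set()] arguments) or `paths` (`counts`,
#' `sheet`, `lengths`, optional `spike_design`, optional `utr_fasta`),
#' together with optional `thresholds` (`tpm_filter` = 5, `alpha` = 0.05,
#' `q_yrs` = 0.2, `p_report` = 0.01), `flags` (`welch` = FALSE, `ruv_k` = 0,
#' `uniform_bg` = FALSE), `seed` and `out`.
#'
#' @param config list or path to a YAML file.
#' @return validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) fs_stop("config must be a list or a YAML path", "config")
  has_sim <- !is.null(config$simulation)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths)
    fs_stop("config must contain exactly one of 'simulation' or 'paths'", "config")
  th <- config$thresholds %||% list()
  th$tpm_filter <- th$tpm_filter %||% 5
  th$alpha <- th$alpha %||% 0.05
  th$q_yrs <- th$q_yrs %||% 0.2
  th$p_report <- th$p_report %||% 0.01
  if (th$tpm_filter < 0) fs_stop("tpm_filter must be >= 0", "config")
  if (th$alpha <= 0 || th$alpha > 1) fs_stop("alpha must be in (0, 1]", "config")
  if (th$q_yrs <= 0 || th$q_yrs > 1) fs_stop("q_yrs must be in (0, 1]", "config")
  if (th$p_report <= 0 || th$p_report > 1) fs_stop("p_report must be in (0, 1]", "config")
  config$thresholds <- th
  fl <- config$flags %||% list()
  fl$welch <- isTRUE(fl$welch)
  fl$ruv_k <- fl$ruv_k %||% 0
  fl$uniform_bg <- isTRUE(fl$uniform_bg)
  config$flags <- fl
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("pipeline_config", "list"))
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canon(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full fractionation analysis pipeline
#'
#' Executes every stage on either a simulated or a file-based experiment
#' and writes six result TSVs (`occupancy.tsv`, `tests.tsv`, `targets.tsv`,
#' `differential.tsv`, `motif_hits.tsv`, `motif_summary.tsv`) plus
#' `manifest.json` (package version, seed, config hash, thresholds, file
#' checksums) into the output directory. A stage failure aborts with a
#' stage-named diagnostic and removes any partial outputs.
#'
#' @param config a [pipeline_config()], a plain list, or a YAML path.
#' @param out output directory (overrides `config$out`).
#' @return the output directory, invisibly; the computed objects are
#'   attached as the attribute `"results"`.
#' @export
run_pipeline <- function(config, out = NULL) {
  config <- pipeline_config(config)
  out <- out %||% config$out
  if (is.null(out)) fs_stop("no output directory given", "config")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  hash <- config_hash(config)
  seed <- config$seed
  th <- config$thresholds
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_result_tsv(df, path, seed = seed, config_hash = hash)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      fs_stop(paste0("stage '", name, "': ", conditionMessage(e)), "pipeline")
    })
  }

  inputs <- stage("input", {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      utr_args <- sim_args$utr
      sim_args$utr <- NULL
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_experiment(do.call(sim_config, sim_args))
      utrs <- NULL
      if (!is.null(utr_args)) {
        utr_args$seed <- utr_args$seed %||% (seed + 1L)
        utrs <- do.call(generate_utr_set, utr_args)$utrs
      }
      list(exp = sim$experiment, truth = sim$truth, utrs = utrs,
           design = sim$truth$config$spike_design)
    } else {
      p <- config$paths
      exp <- read_experiment(p$counts, p$sheet, p$lengths,
                             spikeins = p$spikeins %||% "ERCC-")
      design <- if (!is.null(p$spike_design)) read_spikein_design(p$spike_design)
      utrs <- if (!is.null(p$utr_fasta)) read_utr_fasta(p$utr_fasta)
      list(exp = exp, truth = NULL, utrs = utrs, design = design)
    }
  })

  tpm <- stage("normalize", {
    tp <- compute_tpm(inputs$exp)
    if (length(inputs$exp$spikein_ids) >= 3) {
      s <- spikein_factors(inputs$exp, inputs$design, ruv_k = config$flags$ruv_k)
      tp <- apply_factors(tp, s)
    }
    tp
  })

  genes <- stage("filter", filter_expressed(tpm, threshold = th$tpm_filter))
  occ <- stage("occupancy", compute_occupancy(tpm, genes = genes))
  tests <- stage("tests", occupancy_tests(occ, welch = config$flags$welch))
  ratios <- stage("ratios", polysome_mrnp_ratio(occ))

  targets <- stage("targets", {
    mutants <- intersect(unique(tests$genotype), "CompoundHet")
    mutant <- if (length(mutants)) "CompoundHet" else unique(tests$genotype)[1]
    pm <- tests[tests$genotype == mutant & tests$fraction == "mRNP", ]
    pp <- tests[tests$genotype == mutant & tests$fraction == "polysome", ]
    high_confidence_targets(setNames(pm$p, pm$gene_id),
                            setNames(pp$p, pp$gene_id),
                            alpha = th$alpha, ratios = ratios,
                            mutant = mutant)
  })

  de <- stage("differential", {
    mutants <- setdiff(unique(inputs$exp$sheet$genotype), "WT")
    do.call(rbind, lapply(mutants, function(G) {
      d <- differential_total(tpm, genotype = G, genes = genes,
                              welch = config$flags$welch)
      cbind(genotype = G, d)
    }))
  })

  motif <- stage("motif", {
    if (is.null(inputs$utrs)) {
      list(hits = data.frame(transcript_id = character(), start = integer(),
                             end = integer(), matched = character(),
                             score_bits = numeric(), p = numeric(), q = numeric()),
           summary = data.frame(set = character(), n_utrs = integer(),
                                frac_with_hit = numeric(),
                                mean_canonical = numeric(),
                                n_with_canonical = integer()))
    } else {
      bg <- if (config$flags$uniform_bg) uniform_background()
      hits <- scan_utrs(inputs$utrs, bg = bg,
                        report_threshold_p = th$p_report)
      summ <- compare_utr_sets(list(utrs = inputs$utrs), bg = bg,
                               q_threshold = th$q_yrs,
                               report_threshold_p = th$p_report)
      list(hits = hits, summary = summ)
    }
  })

  stage("write", {
    emit(occ$replicates, "occupancy.tsv")
    emit(tests, "tests.tsv")
    emit(as.data.frame(targets), "targets.tsv")
    emit(de, "differential.tsv")
    emit(motif$hits, "motif_hits.tsv")
    emit(motif$summary, "motif_summary.tsv")
    manifest <- list(package = "fracseq",
                     version = as.character(packageVersion("fracseq")),
                     seed = seed, config_hash = hash, thresholds = th,
                     flags = config$flags,
                     files = as.list(setNames(unname(tools::md5sum(written)),
                                              basename(written))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  res <- list(experiment = inputs$exp, truth = inputs$truth, tpm = tpm,
              genes = genes, occupancy = occ, tests = tests, ratios = ratios,
              targets = targets, differential = de, motif = motif)
  invisible(structure(out, results = res))
}
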