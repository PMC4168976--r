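read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]]
  else if (!is.null(default)) default
  else stop("missing required config key: ", key)
}

write_manifest <- function(path, inputs, params) {
  hashes <- lapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_)
  yaml::write_yaml(list(inputs = inputs, input_md5 = hashes,
                        parameters = params,
                        package_version =
                          as.character(utils::packageVersion("tifa")),
                        r_version = R.version.string,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                   path)
  invisible(path)
}

load_dataset <- function(config) {
  genome <- read_genome(cfg_get(config, "genome"),
                        circular = cfg_get(config, "circular", TRUE))
  genes <- read_genes(cfg_get(config, "genes"))
  records <- read_insertions(cfg_get(config, "insertions"))
  sites <- find_ta_sites(genome)
  flt <- filter_insertions(records, sites,
                           min_reads = cfg_get(config, "min_reads", 8))
  sites <- combine_samples(sites, flt$retained)
  asg <- assign_sites(sites, genes,
                      terminal_frac = cfg_get(config, "terminal_frac",
                                              0.02))
  list(genome = genome, sites = asg$ta_sites, genes = asg$genes,
       filter_report = flt$report, retained = flt$retained)
}

#' Fit and write the insertion-bias model
#'
#' Pipeline stage over a YAML/list config with keys `genome`, `genes`,
#' `insertions`, `out_dir` and optional `window`, `step`, `min_reads`,
#' `terminal_frac`. Writes `bias_model.yaml` and a run manifest.
#'
#' @param config YAML path or list.
#' @return the fitted `bias_model`, invisibly.
#' @export
run_bias <- function(config) {
  config <- read_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(config)
  model <- fit_bias_model(ds$sites, ds$genes,
                          window = cfg_get(config, "window", 20000),
                          step = cfg_get(config, "step", 2000))
  write_bias_model(model, file.path(out_dir, "bias_model.yaml"))
  write_manifest(file.path(out_dir, "manifest_bias.yaml"),
                 inputs = config[c("genome", "genes", "insertions")],
                 params = list(window = cfg_get(config, "window", 20000),
                               step = cfg_get(config, "step", 2000),
                               min_reads = cfg_get(config, "min_reads", 8),
                               filter_report =
                                 as.list(ds$filter_report)))
  invisible(model)
}

#' Call essentiality and write the results table
#'
#' Config keys as in [run_bias()] plus `expected_fp` (default 1) and
#' optionally `operons` (TSV path) for polar-effect flagging. Writes
#' `results.tsv`, its calibration YAML, and a manifest.
#'
#' @param config YAML path or list.
#' @return the `tifa_result`, invisibly.
#' @export
run_call <- function(config) {
  config <- read_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(config)
  model <- fit_bias_model(ds$sites, ds$genes,
                          window = cfg_get(config, "window", 20000),
                          step = cfg_get(config, "step", 2000))
  res <- tifa_call(ds$sites, ds$genes, model,
                   expected_fp = cfg_get(config, "expected_fp", 1))
  if (!is.null(config$operons)) {
    res <- polar_filter(res, read_operons(config$operons))
  } else {
    res$polar_flag <- FALSE
  }
  write_tifa_result(res, file.path(out_dir, "results.tsv"))
  write_manifest(file.path(out_dir, "manifest_call.yaml"),
                 inputs = config[intersect(names(config),
                                           c("genome", "genes",
                                             "insertions", "operons"))],
                 params = list(expected_fp = cfg_get(config,
                                                     "expected_fp", 1),
                               c_ess = as.numeric(attr(res, "c_ess")),
                               c_non = as.numeric(attr(res, "c_non")),
                               rho = as.numeric(attr(res, "rho"))))
  invisible(res)
}

#' Monte Carlo self-validation of the fitted model
#'
#' Config keys as in [run_bias()] plus `reps` (default 1000) and `seed`.
#' Writes the NDE histogram table (`nde_histogram.tsv`) and a manifest.
#'
#' @param config YAML path or list.
#' @return the histogram data.frame, invisibly.
#' @export
run_validate <- function(config) {
  config <- read_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(config)
  model <- fit_bias_model(ds$sites, ds$genes,
                          window = cfg_get(config, "window", 20000),
                          step = cfg_get(config, "step", 2000))
  hist <- nde_distribution(ds$sites, ds$genes, model,
                           reps = cfg_get(config, "reps", 1000),
                           seed = cfg_get(config, "seed", 1L))
  utils::write.table(hist, file.path(out_dir, "nde_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest_validate.yaml"),
                 inputs = config[c("genome", "genes", "insertions")],
                 params = list(reps = cfg_get(config, "reps", 1000),
                               seed = cfg_get(config, "seed", 1L)))
  invisible(hist)
}

#' FBA single-gene deletions and TIFA comparison
#'
#' Config keys: `model` (JSON), optional `medium` (TSV), optional
#' `tifa_results` (TSV from [run_call()]), `out_dir`, `threshold`
#' (default 0.01). Writes `deletions.tsv`, optionally
#' `confusion_table.tsv`, and a manifest.
#'
#' @param config YAML path or list.
#' @return the deletions data.frame, invisibly.
#' @export
run_fba <- function(config) {
  config <- read_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- read_fba_model(cfg_get(config, "model"))
  medium <- if (!is.null(config$medium)) read_medium(config$medium)
  del <- single_gene_deletions(model, medium,
                               threshold = cfg_get(config, "threshold",
                                                   0.01))
  utils::write.table(del, file.path(out_dir, "deletions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config$tifa_results)) {
    res <- utils::read.delim(config$tifa_results,
                             stringsAsFactors = FALSE)
    if ("polar_flag" %in% names(res))
      res <- res[!res$polar_flag | res$call != "essential", ,
                 drop = FALSE]
    ct <- confusion_table(stats::setNames(res$call, res$gene_id),
                          stats::setNames(del$call_1pct, del$gene))
    utils::write.table(
      data.frame(row = c("tifa_essential", "tifa_nonessential"),
                 agree = c(ct$counts["ess_agree"],
                           ct$counts["non_agree"]),
                 disagree = c(ct$counts["ess_disagree"],
                              ct$counts["non_disagree"]),
                 pct_true = c(ct$pct_true_essential,
                              ct$pct_true_nonessential)),
      file.path(out_dir, "confusion_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(file.path(out_dir, "manifest_fba.yaml"),
                 inputs = config[intersect(names(config),
                                           c("model", "medium",
                                             "tifa_results"))],
                 params = list(threshold = cfg_get(config, "threshold",
                                                   0.01)))
  invisible(del)
}

#' Generate and write a synthetic dataset
#'
#' Config keys: `out_dir`, `seed`, and any of the generator parameters
#' (`length`, `ta_density`, `n_genes`, `m`, `residual_rate`,
#' `non_ta_rate`, `essential_frac`, `loc_coeffs`, `spread`). Writes the
#' genome FASTA, gene/operon TSVs, insertion TSV, truth manifest, and a
#' run manifest.
#'
#' @param config YAML path or list.
#' @return list with the `synthetic_genome` and `synthetic_library`,
#'   invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_get(config, "seed", 1L)
  gen <- generate_genome(seed = seed,
                         length = cfg_get(config, "length", 5e6),
                         ta_density = cfg_get(config, "ta_density",
                                              0.032),
                         n_genes = cfg_get(config, "n_genes", 4200))
  n_ess <- round(cfg_get(config, "essential_frac", 0.065) *
                 nrow(gen$genes))
  set.seed(seed + 1L)
  ess_ids <- sample(gen$genes$locus_id, n_ess)
  lc <- unlist(cfg_get(config, "loc_coeffs",
                       list(a = 0.0032, b = 0.0081, c = 0.1615)))
  lib <- generate_library(
    gen, loc_coeffs = lc,
    motif_spectrum = synthetic_motif_spectrum(seed,
                                              spread = cfg_get(config,
                                                               "spread",
                                                               10)),
    essential_ids = ess_ids,
    residual_rate = cfg_get(config, "residual_rate", 0.1),
    m = cfg_get(config, "m", 40000),
    non_ta_rate = cfg_get(config, "non_ta_rate", 0.05),
    seed = seed)
  write_genome_files(gen, out_dir)
  write_library_files(lib, out_dir)
  write_manifest(file.path(out_dir, "manifest_simulate.yaml"),
                 inputs = list(),
                 params = lib$truth)
  invisible(list(genome = gen, library = lib))
}

#' Serialize a bias model to YAML
#'
#' @param model `bias_model`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_bias_model <- function(model, path) {
  doc <- list(loc_coeffs = as.list(model$loc_coeffs),
              loc_se = as.list(model$loc_se),
              mean_prob = model$mean_prob, norm = model$norm,
              genome_length = model$genome_length,
              n_sites = model$n_sites, u_sites = model$u_sites,
              m_events = model$m_events,
              motif_probs = lapply(seq_len(nrow(model$motif_probs)),
                                   function(i)
                                     as.list(model$motif_probs[i, ])))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Deserialize a bias model from YAML
#'
#' @param path YAML path written by [write_bias_model()].
#' @return `bias_model`.
#' @export
read_bias_model <- function(path) {
  doc <- yaml::read_yaml(path)
  mp <- do.call(rbind, lapply(doc$motif_probs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure(list(loc_coeffs = unlist(doc$loc_coeffs),
                 loc_se = unlist(doc$loc_se),
                 motif_probs = mp, mean_prob = doc$mean_prob,
                 norm = doc$norm, genome_length = doc$genome_length,
                 n_sites = doc$n_sites, u_sites = doc$u_sites,
                 m_events = doc$m_events),
            class = "bias_model")
}
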