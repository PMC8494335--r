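#' Pipeline configuration
#'
#' Collects paths, thresholds and sampler settings for an end-to-end run.
#' Config can also be loaded from JSON (or YAML when the yaml package is
#' installed) with [read_pipeline_config()].
#'
#' @param variants_dir Directory containing one `<sample>.vcf` per sample.
#' @param reference Path to the reference FASTA.
#' @param sample_sheet Path to the sample sheet TSV.
#' @param out_dir Output directory.
#' @param screen_alpha Dose-response screen threshold.
#' @param fdr_q FDR threshold for comparisons.
#' @param cluster_method `"window"` or `"hmm"`.
#' @param window_bp Window size for the window cluster caller.
#' @param hmm Cluster HMM parameters ([hmm_params()]).
#' @param sampler List with `chains`, `warmup`, `iter`, `prior_lfc_sd`.
#' @param trinuc_target Path to a target trinucleotide frequency TSV for
#'   spectrum adjustment; defaults to the bundled synthetic human-like
#'   table.
#' @param wt_label Reference genotype label.
#' @param fit_all Fit genotypes even if they fail the dose-response screen.
#' @param seed Integer seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(variants_dir, reference, sample_sheet, out_dir,
                            screen_alpha = 0.05, fdr_q = 0.05,
                            cluster_method = "window", window_bp = 1000L,
                            hmm = hmm_params(),
                            sampler = list(chains = 4L, warmup = 1000L,
                                           iter = 1000L, prior_lfc_sd = 3),
                            trinuc_target = system.file(
                              "extdata", "trinuc_freqs_synthetic_human.tsv",
                              package = "radsig"),
                            wt_label = "wild-type", fit_all = FALSE,
                            seed = 1L) {
  cfg <- list(variants_dir = variants_dir, reference = reference,
              sample_sheet = sample_sheet, out_dir = out_dir,
              screen_alpha = screen_alpha, fdr_q = fdr_q,
              cluster_method = cluster_method, window_bp = window_bp,
              hmm = hmm, sampler = sampler, trinuc_target = trinuc_target,
              wt_label = wt_label, fit_all = fit_all,
              seed = as.integer(seed))
  stopifnot(cfg$screen_alpha > 0, cfg$screen_alpha < 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$cluster_method %in% c("window", "hmm"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a JSON (or YAML) config file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$hmm)) raw$hmm <- do.call(hmm_params, raw$hmm)
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on a directory of per-sample VCFs: spectrum
#' construction, dose-response screening, signature-model fitting (over the
#' genotypes passing the screen, unless `fit_all`), genotype comparisons
#' with FDR control, cluster calling and summaries, spectrum adjustment to
#' the target trinucleotide composition, and a run manifest. Re-running
#' with identical inputs, config and seed reproduces every output.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a result bundle: list with the in-memory objects and
#'   `manifest` (also written as JSON to the output directory).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c(cfg$reference, cfg$sample_sheet, cfg$variants_dir))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  scheme <- channel_scheme()

  genome <- .stage("reference", read_reference(cfg$reference))
  metas <- .stage("sample_sheet", read_sample_sheet(cfg$sample_sheet))
  variants <- .stage("variants", {
    recs <- lapply(metas$sample_id, function(id) {
      f <- file.path(cfg$variants_dir, paste0(id, ".vcf"))
      if (!file.exists(f)) stop("missing VCF for sample ", id)
      read_variants(f, id)
    })
    sort_variants(do.call(rbind, c(recs, list(make.row.names = FALSE))))
  })

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  spectra <- .stage("spectra", spectrum_matrix(variants, metas, genome,
                                               scheme))
  write_spectra(spectra, out("spectra.tsv"))

  screen <- .stage("screen",
                   screen_dose_response(spectra, metas, cfg$screen_alpha,
                                        scheme))
  write_table_tsv(screen, out("screen.tsv"))

  keep_genos <- if (cfg$fit_all) unique(metas$genotype)
                else union(cfg$wt_label, screen$genotype[screen$passes])
  fit_metas <- metas[metas$genotype %in% keep_genos, ]
  fit <- .stage("signature_fit", fit_signature_model(
    spectra[fit_metas$sample_id, , drop = FALSE], fit_metas,
    wt_label = cfg$wt_label, chains = cfg$sampler$chains,
    warmup = cfg$sampler$warmup, iter = cfg$sampler$iter,
    seed = cfg$seed, prior_lfc_sd = cfg$sampler$prior_lfc_sd,
    scheme = scheme))
  write_signature_fit(fit, out("signature_fit.json"))

  comparisons <- if (length(fit$genotypes) > 1L)
    .stage("comparisons",
           compare_to_wildtype(fit, cfg$fdr_q,
                               allow_flagged = cfg$fit_all))
  else data.frame()
  write_table_tsv(comparisons, out("comparisons.tsv"))

  calls <- .stage("clusters", detect_clusters(
    variants, metas, method = cfg$cluster_method,
    window_bp = cfg$window_bp, params = cfg$hmm))
  write_clusters_bed(calls, out("clusters.bed"))
  cluster_summary <- .stage("cluster_summary",
                            summarize_clusters(calls, variants, metas))
  write_table_tsv(cluster_summary, out("cluster_summary.tsv"))

  humanized <- .stage("humanize", {
    from <- trinuc_frequencies(genome, label = "reference")
    to <- read_trinuc_freqs(cfg$trinuc_target)
    wt_ids <- metas$sample_id[metas$genotype == cfg$wt_label]
    wt_spec <- colSums(spectra[wt_ids, seq_len(119L), drop = FALSE])
    adjust_spectrum(wt_spec, from, to, scheme)
  })
  write_table_tsv(data.frame(channel = scheme$labels,
                             adjusted = as.numeric(humanized)),
                  out("humanized_spectrum.tsv"))

  cfg_json <- out("config.json")
  cfg_ser <- cfg
  cfg_ser$hmm <- unclass(cfg_ser$hmm)
  jsonlite::write_json(unclass(cfg_ser), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radsig")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    n_samples = nrow(metas), n_variants = nrow(variants),
    genotypes_fitted = fit$genotypes,
    outputs = c("spectra.tsv", "screen.tsv", "signature_fit.json",
                "comparisons.tsv", "clusters.bed", "cluster_summary.tsv",
                "humanized_spectrum.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(spectra = spectra, screen = screen, fit = fit,
                 comparisons = comparisons, clusters = calls,
                 cluster_summary = cluster_summary, humanized = humanized,
                 manifest = manifest))
}
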