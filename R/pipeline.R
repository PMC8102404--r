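# End-to-end orchestration.
#
# A run is described by a flat config (R list or JSON file) with per-stage
# sections; stages execute in dependency order, every output lands inside
# `output_dir`, and a manifest records parameters, seeds, input hashes and
# the package version so an identical config reproduces identical outputs.

#' Default pipeline configuration
#'
#' @param output_dir where all stage outputs are written.
#' @param seed master seed; per-stage seeds derive from it deterministically.
#' @return nested config list (stages: `network`, `sample`, `diffflux`,
#'   `metabolomics`, `metstats`, `lipids`, `chemml`).
#' @export
default_config <- function(output_dir = "fluxlip_run", seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    stages = c("network", "sample", "diffflux", "metabolomics", "metstats",
               "lipids", "chemml"),
    network = list(n_pathways = 3, branch_count = 1, ko_pathway = 2),
    sample = list(n_samples = 500, thinning = 10, normalization = "l1"),
    diffflux = list(alpha = 0.001, fc_hi = 2, fc_lo = 0.5,
                    affected_mode = "all"),
    metabolomics = list(n_metabolites = 342, n_per_group = 5,
                        planted_fraction = 0.35, effect_fold = 4,
                        sigma = 0.3, missing_rate = 0.05),
    metstats = list(test = "welch", case = "KO", control = "WT",
                    strict = FALSE),
    lipids = list(n_elevated = 86, n_decreased = 40),
    chemml = list(model = "random_forest", scheme = "downsample",
                  target_features = 6, corr_cutoff = 0.9)
  )
}

#' Load a pipeline config from JSON
#'
#' Values present in the file override [default_config()] defaults.
#'
#' @param path JSON config path.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config()
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]])
      } else over[[k]]
    }
    base
  }
  merge_cfg(cfg, user)
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order. Every file written is
#' listed in `manifest.json` with its md5 hash, the parameters actually
#' used, and all seeds, so reruns with the same config are bit-identical for
#' the deterministic stages.
#'
#' @param config config list (see [default_config()]) or path to a JSON
#'   config.
#' @param input_files optional named list of user-supplied inputs replacing
#'   synthetic stages (paths are validated before any stage runs).
#' @return the manifest (invisibly); also written to
#'   `file.path(output_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = default_config(), input_files = list()) {
  if (is.character(config)) config <- read_config(config)
  for (f in unlist(input_files)) {
    if (!file.exists(f)) stop("configured input does not exist: ", f)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("fluxlip")),
                   seed = seed, stages = list(), files = list())
  log_msg <- function(...) message("[fluxlip] ", ...)
  register <- function(path, stage) {
    manifest$files[[basename(path)]] <<- list(
      stage = stage, md5 = unname(tools::md5sum(path)))
  }
  stages <- config$stages
  state <- list()

  if ("network" %in% stages) {
    p <- config$network
    log_msg("network: pathways=", p$n_pathways, " ko_pathway=", p$ko_pathway)
    net <- make_toy_network(p$n_pathways, p$branch_count, p$ko_pathway,
                            seed = seed)
    write_model_json(net$model, file.path(out_dir, "model_wt.json"))
    write_model_json(net$ko_model, file.path(out_dir, "model_ko.json"))
    writeLines(net$ground_truth, file.path(out_dir, "ground_truth_reactions.txt"))
    register(file.path(out_dir, "model_wt.json"), "network")
    register(file.path(out_dir, "model_ko.json"), "network")
    register(file.path(out_dir, "ground_truth_reactions.txt"), "network")
    manifest$stages$network <- p
    state$net <- net
  }
  if ("sample" %in% stages) {
    if (is.null(state$net)) stop("stage 'sample' needs upstream 'network' outputs")
    p <- config$sample
    log_msg("sample: n=", p$n_samples, " thinning=", p$thinning)
    for (cond in c("wt", "ko")) {
      model <- if (cond == "wt") state$net$model else state$net$ko_model
      s <- sample_fluxes(model, p$n_samples, seed = seed + match(cond, c("wt", "ko")),
                         thinning = p$thinning, condition = cond)
      s <- normalize_samples(s, p$normalization)
      write_sample_set(s, file.path(out_dir, paste0("samples_", cond, ".tsv")))
      register(file.path(out_dir, paste0("samples_", cond, ".tsv")), "sample")
      state[[paste0("samples_", cond)]] <- s
    }
    manifest$stages$sample <- p
  }
  if ("diffflux" %in% stages) {
    if (is.null(state$samples_wt)) stop("stage 'diffflux' needs upstream 'sample' outputs")
    p <- config$diffflux
    log_msg("diffflux: alpha=", p$alpha)
    res <- call_altered_reactions(state$samples_wt, state$samples_ko,
                                  alpha = p$alpha, fc_hi = p$fc_hi,
                                  fc_lo = p$fc_lo)
    rl <- rollup(res, state$net$model, affected_mode = p$affected_mode)
    write_diff_flux(res, file.path(out_dir, "diff_flux.tsv"), rl)
    register(file.path(out_dir, "diff_flux.tsv"), "diffflux")
    manifest$stages$diffflux <- c(p, list(n_altered = rl$n_altered))
    state$diff <- res
    state$rollup <- rl
  }
  if ("metabolomics" %in% stages) {
    p <- config$metabolomics
    log_msg("metabolomics: ", p$n_metabolites, " metabolites")
    met <- make_metabolomics(p$n_metabolites, p$n_per_group,
                             p$planted_fraction, p$effect_fold, p$sigma,
                             p$missing_rate, seed = seed + 10)
    ab <- data.frame(sample_id = rownames(met$table$abundance),
                     met$table$abundance, check.names = FALSE)
    utils::write.table(ab, file.path(out_dir, "abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    register(file.path(out_dir, "abundance.tsv"), "metabolomics")
    manifest$stages$metabolomics <- p
    state$met <- met
  }
  if ("metstats" %in% stages) {
    if (is.null(state$met)) stop("stage 'metstats' needs upstream 'metabolomics' outputs")
    p <- config$metstats
    log_msg("metstats: test=", p$test)
    st <- metabolite_stats(state$met$table, case = p$case,
                           control = p$control, test = p$test)
    en <- subpathway_enrichment(st, strict = isTRUE(p$strict))
    utils::write.table(st, file.path(out_dir, "metabolite_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(en, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    register(file.path(out_dir, "metabolite_stats.tsv"), "metstats")
    register(file.path(out_dir, "enrichment.tsv"), "metstats")
    manifest$stages$metstats <- p
    state$stats <- st
  }
  if ("lipids" %in% stages) {
    p <- config$lipids
    log_msg("lipids: ", p$n_elevated, "/", p$n_decreased)
    recs <- make_lipid_classes(p$n_elevated, p$n_decreased, seed = seed + 20)
    utils::write.table(recs$table, file.path(out_dir, "lipids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(name = rownames(recs$descriptors), recs$descriptors,
                 check.names = FALSE),
      file.path(out_dir, "descriptors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    register(file.path(out_dir, "lipids.tsv"), "lipids")
    register(file.path(out_dir, "descriptors.tsv"), "lipids")
    manifest$stages$lipids <- p
    state$recs <- recs
  }
  if ("chemml" %in% stages) {
    if (is.null(state$recs)) stop("stage 'chemml' needs upstream 'lipids' outputs")
    p <- config$chemml
    log_msg("chemml: model=", p$model, " scheme=", p$scheme)
    feats <- select_features(state$recs, p$target_features, p$corr_cutoff)
    report <- loo_evaluate(state$recs, feats, p$model, seed = seed + 30,
                           scheme = p$scheme)
    fv <- freeviz_project(state$recs, feats, seed = seed + 31)
    jsonlite::write_json(
      list(model = report$model, scheme = report$scheme, seed = report$seed,
           features = feats, accuracy = report$accuracy,
           confusion = as.data.frame(report$confusion),
           misclassified = report$misclassified),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(name = rownames(fv$embedding), fv$embedding),
      file.path(out_dir, "freeviz_embedding.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    register(file.path(out_dir, "classification_report.json"), "chemml")
    register(file.path(out_dir, "freeviz_embedding.tsv"), "chemml")
    manifest$stages$chemml <- c(p, list(features = feats,
                                        accuracy = report$accuracy))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
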