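#' Default pipeline configuration
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param stages character vector of stages to run, in dependency order.
#' @return a nested list of class `run_config` (YAML-serializable).
#' @export
default_run_config <- function(seed = 1L,
                               stages = c("simulate", "match", "diversity",
                                          "diff", "associate", "classify")) {
  structure(list(
    seed = as.integer(seed),
    stages = stages,
    inputs = list(taxa = NULL, pathways = NULL, metabolites = NULL,
                  design = NULL, tree = NULL, pairs = NULL,
                  annotation = NULL),
    simulate = list(),
    match = list(ev_threshold = 0.85, caliper = 0.25, ratio = 2,
                 replacement = TRUE, caliper_scale = "sd"),
    diversity = list(n_permutations = 999, depth = 1e5),
    diff = list(min_fraction = 0.10, alpha = 0.05),
    associate = list(n_permutations = 1000, max_features = 15),
    enrich = list(),
    classify = list(n_folds = 5, num_trees = 500, max_depth = 0,
                    min_node_size = 1, max_candidates = 30)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [default_run_config].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L,
                            stages = user$stages %||%
                              c("simulate", "match", "diversity", "diff",
                                "associate", "classify"))
  for (nm in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

validate_run_config <- function(cfg) {
  stages <- cfg$stages
  known <- c("simulate", "match", "diversity", "diff", "associate", "enrich",
             "classify")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  have_pairs <- "match" %in% stages || !is.null(cfg$inputs$pairs)
  for (st in intersect(c("diff", "associate"), stages))
    if (!have_pairs)
      stop(st, " requires pairs: enable the match stage or provide inputs$pairs")
  if ("classify" %in% stages && !"diff" %in% stages)
    stop("classify requires the diff stage (candidate features)")
  if (!"simulate" %in% stages) {
    need <- c("taxa", "pathways", "design")
    for (nm in need) {
      p <- cfg$inputs[[nm]]
      if (is.null(p)) stop("without the simulate stage, inputs$", nm, " is required")
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  if ("enrich" %in% stages) {
    p <- cfg$inputs$annotation
    if (is.null(p) || !file.exists(p))
      stop("enrich requires inputs$annotation (feature TAB term map)")
  }
  invisible(cfg)
}

#' Run the end-to-end analysis pipeline
#'
#' Stages (in dependency order): `simulate` (or load the input tables),
#' `match` (quasi-paired cohort), `diversity`, `diff` (paired differential
#' tables for taxa and metabolites), `associate` (signed-NMI trend heatmap
#' input over the differential features), optional `enrich`, and `classify`
#' (RF recursive feature elimination over the differential features). Every
#' stage writes plain TSVs so each intermediate is inspectable; a manifest with
#' per-stage file hashes and timings is written even when a stage fails.
#'
#' @param config a `run_config` list, or path to a YAML file.
#' @param out_dir output directory.
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package_version = as.character(utils::packageVersion("qpcohort")),
                   seed = seed, stages = list())
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  state <- new.env(parent = emptyenv())
  finish <- function(st, t0, files) {
    manifest$stages[[st]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      outputs = as.list(tools::md5sum(files)))
    logf("stage %-10s done in %.1fs (%d files)", st,
         manifest$stages[[st]]$seconds, length(files))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  on.exit(write_manifest())

  result <- tryCatch({
    for (st in config$stages) {
      t0 <- as.numeric(Sys.time())
      files <- switch(st,
        simulate = stage_simulate(config, seed, out_dir, state),
        match = stage_match(config, out_dir, state),
        diversity = stage_diversity(config, seed, out_dir, state),
        diff = stage_diff(config, out_dir, state),
        associate = stage_associate(config, seed, out_dir, state),
        enrich = stage_enrich(config, out_dir, state),
        classify = stage_classify(config, seed, out_dir, state))
      finish(st, t0, files)
    }
    manifest$status <- "ok"
    manifest
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  })
  invisible(result)
}

load_inputs <- function(config, state) {
  if (is.null(state$taxa)) {
    state$taxa <- read_abundance_table(config$inputs$taxa, dialect = "plain",
                                       scale_tag = "percent")
    state$pathways <- read_abundance_table(config$inputs$pathways,
                                           dialect = "plain",
                                           scale_tag = "percent")
    if (!is.null(config$inputs$metabolites))
      state$metabolites <- read_abundance_table(config$inputs$metabolites,
                                                dialect = "plain",
                                                scale_tag = "count")
    state$design <- read_design(config$inputs$design)
    if (!is.null(config$inputs$tree))
      state$tree <- read_newick(config$inputs$tree)
    if (!is.null(config$inputs$pairs))
      state$pairs <- read_pairs(config$inputs$pairs)
  }
  invisible(state)
}

stage_simulate <- function(config, seed, out_dir, state) {
  args <- config$simulate
  args$seed <- stream_seed(seed, "simulate")
  sim <- generate_cohort(do.call(sim_config, args))
  state$taxa <- sim$taxa
  state$pathways <- sim$pathways
  state$metabolites <- sim$metabolites
  state$design <- sim$design
  state$truth <- sim$truth
  state$tree <- generate_tree(ncol(sim$taxa$values),
                              seed = stream_seed(seed, "tree"),
                              tip_labels = feature_ids(sim$taxa))
  write_cohort(sim, out_dir, tree = state$tree)
}

stage_match <- function(config, out_dir, state) {
  load_inputs(config, state)
  mc <- config$match
  fit <- quasi_pair(state$pathways, state$design,
                    ev_threshold = mc$ev_threshold, caliper = mc$caliper,
                    ratio = mc$ratio, replacement = mc$replacement,
                    caliper_scale = mc$caliper_scale)
  state$pairs <- fit$pairs
  state$quasi_pair <- fit
  c(write_pairs(fit$pairs, file.path(out_dir, "pairs.tsv")),
    write_results(as.data.frame(fit$balance), file.path(out_dir, "balance.tsv")))
}

stage_diversity <- function(config, seed, out_dir, state) {
  load_inputs(config, state)
  dv <- config$diversity
  res <- diversity_summary(state$taxa, state$design, tree = state$tree,
                           depth = dv$depth, n_permutations = dv$n_permutations,
                           seed = stream_seed(seed, "diversity"))
  files <- c(
    write_results(res$alpha, file.path(out_dir, "alpha_diversity.tsv")),
    write_results(dist_to_df(res$bray), file.path(out_dir, "bray_curtis.tsv")),
    write_results(data.frame(sample_id = rownames(res$pcoa$coordinates),
                             res$pcoa$coordinates),
                  file.path(out_dir, "pcoa.tsv")),
    write_results(data.frame(pseudo_F = res$permanova$pseudo_F,
                             p_value = res$permanova$p_value,
                             n_permutations = res$permanova$n_permutations,
                             alpha_rank_sum_p = res$alpha_test$p_value),
                  file.path(out_dir, "permanova.tsv")))
  if (!is.null(res$unifrac))
    files <- c(files, write_results(dist_to_df(res$unifrac),
                                    file.path(out_dir, "unifrac.tsv")))
  files
}

dist_to_df <- function(d) {
  m <- as.matrix(d)
  data.frame(sample_id = rownames(m), m, check.names = FALSE)
}

stage_diff <- function(config, out_dir, state) {
  load_inputs(config, state)
  dc <- config$diff
  filtered <- prevalence_filter(state$taxa, min_fraction = dc$min_fraction)
  state$diff_taxa <- differential_table(filtered, state$pairs, alpha = dc$alpha)
  files <- write_results(as.data.frame(state$diff_taxa),
                         file.path(out_dir, "diff_taxa.tsv"))
  if (!is.null(state$metabolites)) {
    state$diff_metabolites <- differential_table(state$metabolites, state$pairs,
                                                 alpha = dc$alpha)
    files <- c(files, write_results(as.data.frame(state$diff_metabolites),
                                    file.path(out_dir, "diff_metabolites.tsv")))
  }
  files
}

top_features <- function(diff, k) {
  sig <- diff$feature_id[diff$significant]
  if (length(sig) < 2) sig <- diff$feature_id[seq_len(min(k, nrow(diff)))]
  utils::head(sig, k)
}

stage_associate <- function(config, seed, out_dir, state) {
  load_inputs(config, state)
  ac <- config$associate
  if (is.null(state$diff_taxa))
    stop("associate requires the diff stage results")
  fa <- top_features(state$diff_taxa, ac$max_features)
  fb <- if (!is.null(state$diff_metabolites))
    top_features(state$diff_metabolites, ac$max_features)
  else utils::head(feature_ids(state$metabolites), ac$max_features)
  assoc <- associate_trends(state$taxa[, fa], state$metabolites[, fb],
                            state$pairs, n_permutations = ac$n_permutations,
                            seed = stream_seed(seed, "associate"))
  write_results(as.data.frame(assoc), file.path(out_dir, "associations.tsv"))
}

stage_enrich <- function(config, out_dir, state) {
  load_inputs(config, state)
  ann <- utils::read.table(config$inputs$annotation, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  background <- feature_ids(state$taxa)
  selected <- state$diff_taxa$feature_id[state$diff_taxa$significant]
  enr <- hypergeom_enrichment(intersect(selected, background), background, ann)
  write_results(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
}

stage_classify <- function(config, seed, out_dir, state) {
  load_inputs(config, state)
  cc <- config$classify
  cand_t <- top_features(state$diff_taxa, cc$max_candidates %/% 2)
  cand_m <- if (!is.null(state$diff_metabolites))
    top_features(state$diff_metabolites, cc$max_candidates %/% 2)
  else character(0)
  x <- cbind(state$taxa$values[, cand_t, drop = FALSE],
             if (length(cand_m)) state$metabolites$values[
               rownames(state$taxa$values), cand_m, drop = FALSE])
  labels <- as.character(state$design[rownames(x), "group"])
  report <- rfe_select(x, labels, n_folds = cc$n_folds,
                       seed = stream_seed(seed, "classify"),
                       num_trees = cc$num_trees, max_depth = cc$max_depth,
                       min_node_size = cc$min_node_size)
  state$classifier <- report
  c(write_results(report$curve, file.path(out_dir, "rfe_curve.tsv")),
    write_results(report$roc, file.path(out_dir, "roc.tsv")),
    write_results(data.frame(feature_id = report$selected_features,
                             final_auc = report$final_auc),
                  file.path(out_dir, "selected_features.tsv")))
}
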