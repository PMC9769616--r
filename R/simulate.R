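#' Configuration for the synthetic case-control cohort simulator
#'
#' Defaults emulate the shape of a confounded case-control gut-microbiome /
#' serum-metabolome cohort: 42 disease and 46 control samples, compositional
#' zero-inflated taxon and pathway profiles, clinical covariates whose group
#' imbalance is transmitted to the pathway table (the confounding that
#' motivates metabolic-background matching), planted group effects on taxa and
#' metabolites, and planted trend couplings between feature pairs.
#'
#' Taxa and pathways are generated on a latent log-normal scale (so planted
#' multiplicative effects have interpretable log-fold sizes), zero-inflated,
#' then closed to percent compositions. Metabolites are positive log-normal
#' concentrations, not closed.
#'
#' @param n_disease,n_control group sizes.
#' @param n_taxa,n_pathways,n_metabolites feature counts.
#' @param zero_inflation Bernoulli zero rate applied to taxa cells before
#'   closure, in `[0, 1)`.
#' @param zero_inflation_pathway zero rate for pathway cells; much lower by
#'   default (functional redundancy makes pathway tables dense).
#' @param log_sd residual standard deviation of latent log-abundances (taxa and
#'   metabolites); pathways use `log_sd_pathway`.
#' @param log_sd_pathway residual sd for pathways (smaller: functional profiles
#'   are more stable across individuals than taxonomic ones).
#' @param taxa_effects data.frame `feature`, `log2_fc`: multiplicative group
#'   effects (disease multiplied by `2^log2_fc`). `NULL` for none; the default
#'   plants 20 differential taxa at |log2 fold change| 1.5.
#' @param metabolite_effects same, for metabolites (10 planted by default).
#' @param covariates data.frame `name`, `disease_mean`, `disease_sd`,
#'   `control_mean`, `control_sd` describing clinical covariates; the defaults
#'   make age and fasting blood glucose (FBG) imbalanced between groups while
#'   TG and HDL are balanced.
#' @param pathway_coupling data.frame `covariate`, `factor`, `strength`
#'   (strength in `[0,1]`): covariates drive latent pathway factors, each
#'   loading on a block of pathways. This is what makes the covariate imbalance
#'   visible to the metabolic background and hence removable by matching.
#' @param taxa_confounding either a data.frame `feature`, `covariate`,
#'   `strength` (per-standardized-unit additive effect on the log abundance),
#'   the string `"mask"` (default: derive, for every planted taxon effect, an
#'   age coupling whose expected between-group contribution cancels the planted
#'   effect, so conventional unpaired testing is blind to it), or `NULL`.
#' @param couplings data.frame `feature_a` (taxon), `feature_b` (metabolite),
#'   `sign` (+1/-1), `strength` in `[0,1]`: trend couplings implemented as a
#'   shared per-sample latent entering both features' log-abundances with
#'   weight `strength` (own noise scaled by `sqrt(1 - strength^2)`, so
#'   `strength` acts as a correlation weight).
#' @param seed integer; fixes the full output byte-for-byte. All randomness is
#'   derived from it through named substreams (one per table), so adding a
#'   table does not perturb the others.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_disease = 42, n_control = 46,
                       n_taxa = 150, n_pathways = 120, n_metabolites = 80,
                       zero_inflation = 0.1,
                       log_sd = 1.0, log_sd_pathway = 0.2,
                       zero_inflation_pathway = 0.02,
                       taxa_effects = NULL,
                       metabolite_effects = NULL,
                       covariates = NULL,
                       pathway_coupling = NULL,
                       taxa_confounding = "mask",
                       couplings = NULL,
                       seed = 1L) {
  if (n_disease < 2 || n_control < 2) stop("group sizes must be >= 2")
  if (n_taxa < 2 || n_pathways < 2 || n_metabolites < 2)
    stop("feature counts must be >= 2")
  if (zero_inflation < 0 || zero_inflation >= 1 ||
      zero_inflation_pathway < 0 || zero_inflation_pathway >= 1)
    stop("zero_inflation must be in [0, 1)")
  taxa_ids <- sprintf("sp%03d", seq_len(n_taxa))
  pathway_ids <- sprintf("pwy%03d", seq_len(n_pathways))
  metab_ids <- sprintf("met%03d", seq_len(n_metabolites))

  if (is.null(taxa_effects)) {
    n_eff <- min(20L, n_taxa)
    taxa_effects <- data.frame(
      feature = taxa_ids[seq_len(n_eff)],
      log2_fc = rep_len(c(1.5, -1.5), n_eff),
      stringsAsFactors = FALSE)
  }
  if (is.null(metabolite_effects)) {
    n_eff <- min(10L, n_metabolites)
    metabolite_effects <- data.frame(
      feature = metab_ids[seq_len(n_eff)],
      log2_fc = rep_len(c(1.5, -1.5), n_eff),
      stringsAsFactors = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- data.frame(
      name = c("age", "FBG", "TG", "HDL"),
      disease_mean = c(61, 6.0, 1.8, 1.10),
      disease_sd   = c(8, 1.0, 0.9, 0.30),
      control_mean = c(55, 5.4, 1.8, 1.10),
      control_sd   = c(8, 0.9, 0.9, 0.30),
      stringsAsFactors = FALSE)
  }
  if (is.null(pathway_coupling)) {
    pathway_coupling <- data.frame(
      covariate = c("age", "FBG"), factor = c(1L, 2L),
      strength = c(0.8, 0.8), stringsAsFactors = FALSE)
  }
  if (is.null(couplings)) {
    na <- max(0L, min(10L, n_taxa - nrow(taxa_effects)))
    nb <- max(0L, min(10L, n_metabolites - nrow(metabolite_effects)))
    n_cp <- min(na, nb)
    couplings <- data.frame(
      feature_a = taxa_ids[nrow(taxa_effects) + seq_len(n_cp)],
      feature_b = metab_ids[nrow(metabolite_effects) + seq_len(n_cp)],
      sign = rep_len(c(1, -1), n_cp),
      strength = rep(0.9, n_cp),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_disease = as.integer(n_disease), n_control = as.integer(n_control),
              n_taxa = as.integer(n_taxa), n_pathways = as.integer(n_pathways),
              n_metabolites = as.integer(n_metabolites),
              zero_inflation = zero_inflation,
              zero_inflation_pathway = zero_inflation_pathway,
              log_sd = log_sd, log_sd_pathway = log_sd_pathway,
              taxa_effects = taxa_effects,
              metabolite_effects = metabolite_effects,
              covariates = covariates, pathway_coupling = pathway_coupling,
              taxa_confounding = taxa_confounding, couplings = couplings,
              taxa_ids = taxa_ids, pathway_ids = pathway_ids,
              metab_ids = metab_ids, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_features <- function(feats, pool, what) {
    missing <- setdiff(feats, pool)
    if (length(missing))
      stop("planted ", what, " on nonexistent feature(s): ",
           paste(missing, collapse = ", "))
  }
  if (nrow(cfg$taxa_effects) > cfg$n_taxa)
    stop("more planted taxa effects than taxa")
  check_features(cfg$taxa_effects$feature, cfg$taxa_ids, "effect")
  check_features(cfg$metabolite_effects$feature, cfg$metab_ids, "effect")
  check_features(cfg$couplings$feature_a, cfg$taxa_ids, "coupling")
  check_features(cfg$couplings$feature_b, cfg$metab_ids, "coupling")
  if (anyDuplicated(c(cfg$couplings$feature_a, cfg$couplings$feature_b)))
    stop("a feature may enter at most one trend coupling")
  if (any(cfg$couplings$strength < 0 | cfg$couplings$strength > 1))
    stop("coupling strengths must be in [0, 1]")
  if (any(cfg$pathway_coupling$strength < 0 | cfg$pathway_coupling$strength > 1))
    stop("pathway coupling strengths must be in [0, 1]")
  bad <- setdiff(cfg$pathway_coupling$covariate, cfg$covariates$name)
  if (length(bad)) stop("pathway coupling on unknown covariate: ", bad[1L])
  invisible(cfg)
}

# Deterministic substream seed derived from the root seed and a stream name;
# keeps every per-table stream independent of the others' draw counts.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483646 + 1)
}

#' Generate a synthetic case-control multi-omic cohort
#'
#' @param config a [sim_config].
#' @return a list of class `sim_cohort` with elements `taxa`, `pathways`,
#'   `metabolites` ([abundance_table]s), `design` ([cohort_design]) and `truth`
#'   (a `truth_sheet` recording every planted effect, confounder and coupling).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_disease + cfg$n_control
  ids <- c(sprintf("D%03d", seq_len(cfg$n_disease)),
           sprintf("C%03d", seq_len(cfg$n_control)))
  group <- rep(c("disease", "control"), c(cfg$n_disease, cfg$n_control))
  is_d <- group == "disease"

  # clinical covariates
  set.seed(stream_seed(cfg$seed, "covariates"))
  cov <- cfg$covariates
  covmat <- matrix(NA_real_, n, nrow(cov), dimnames = list(ids, cov$name))
  for (i in seq_len(nrow(cov))) {
    covmat[is_d, i] <- stats::rnorm(cfg$n_disease, cov$disease_mean[i], cov$disease_sd[i])
    covmat[!is_d, i] <- stats::rnorm(cfg$n_control, cov$control_mean[i], cov$control_sd[i])
  }
  # standardized covariates on the design scale (midpoint / pooled sd), used
  # by all couplings so planted strengths are per-standardized-unit
  mid <- (cov$disease_mean + cov$control_mean) / 2
  sd_pool <- sqrt((cov$disease_sd^2 + cov$control_sd^2) / 2)
  z <- sweep(sweep(covmat, 2, mid), 2, sd_pool, "/")

  # expected standardized group gap per covariate (drives the mask derivation)
  smd_expected <- (cov$disease_mean - cov$control_mean) / sd_pool
  names(smd_expected) <- cov$name

  # "mask" derivation: couple every planted taxon to the pathway-coupled
  # covariates, in the same proportions in which they drive the metabolic
  # background, scaled so the expected between-group contribution cancels the
  # planted effect. Conventional unpaired testing then sees no group signal,
  # while matching on the background aligns exactly this covariate combination
  # within pairs, unmasking the effect for the paired test.
  taxa_conf <- cfg$taxa_confounding
  if (identical(taxa_conf, "mask")) {
    pc_cov <- unique(cfg$pathway_coupling$covariate)
    w <- vapply(pc_cov, function(cv)
      sum(cfg$pathway_coupling$strength[cfg$pathway_coupling$covariate == cv]),
      numeric(1))
    gaps <- smd_expected[pc_cov]
    denom <- sum(w * gaps)
    if (abs(denom) < 1e-8)
      stop("taxa_confounding = 'mask' needs pathway-coupled covariates with ",
           "a nonzero expected group gap")
    taxa_conf <- do.call(rbind, lapply(seq_len(nrow(cfg$taxa_effects)), function(i) {
      beta <- cfg$taxa_effects$log2_fc[i] * log(2)
      data.frame(feature = cfg$taxa_effects$feature[i], covariate = pc_cov,
                 strength = -beta * w / denom, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(taxa_conf) && nrow(taxa_conf)) {
    if (length(setdiff(taxa_conf$feature, cfg$taxa_ids)))
      stop("taxa confounding on nonexistent feature")
    if (length(setdiff(taxa_conf$covariate, cov$name)))
      stop("taxa confounding on unknown covariate")
  }

  # shared latents for trend couplings (one stream, shared across tables)
  set.seed(stream_seed(cfg$seed, "couplings"))
  cp <- cfg$couplings
  u <- if (nrow(cp)) matrix(stats::rnorm(n * nrow(cp)), n, nrow(cp)) else
    matrix(0, n, 0)

  # taxa table
  taxa <- simulate_composition(
    seed = stream_seed(cfg$seed, "taxa"), ids = ids, feat = cfg$taxa_ids,
    base_sd = 1.5, log_sd = cfg$log_sd, zero_inflation = cfg$zero_inflation,
    effect = effect_vector(cfg$taxa_effects, cfg$taxa_ids), is_d = is_d,
    conf = conf_matrix(taxa_conf, cfg$taxa_ids, z),
    coupling = coupling_spec(cp, cfg$taxa_ids, side = "a"), u = u)

  # pathway table: covariate-driven latent factors on pathway blocks
  set.seed(stream_seed(cfg$seed, "pathway_factors"))
  pc <- cfg$pathway_coupling
  n_factor <- max(pc$factor, 0L)
  factors <- matrix(0, n, max(n_factor, 1L))
  if (n_factor > 0) {
    for (f in seq_len(n_factor)) {
      rows <- pc[pc$factor == f, , drop = FALSE]
      drive <- rep(0, n)
      s2 <- 0
      for (i in seq_len(nrow(rows))) {
        drive <- drive + rows$strength[i] * z[, rows$covariate[i]]
        s2 <- s2 + rows$strength[i]^2
      }
      factors[, f] <- drive + sqrt(max(0, 1 - s2)) * stats::rnorm(n)
    }
  }
  # each factor loads on its own block of pathways, leaving the remainder
  # unloaded: compositional closure preserves only contrasts, so a factor
  # loading on every pathway would vanish from the closed table
  block <- max(1L, cfg$n_pathways %/% (2L * max(n_factor, 1L)))
  loadings <- matrix(0, cfg$n_pathways, max(n_factor, 1L))
  if (n_factor > 0)
    for (f in seq_len(n_factor)) {
      idx <- ((f - 1L) * block + 1L):min(f * block, cfg$n_pathways)
      loadings[idx, f] <- 1
    }
  pathways <- simulate_composition(
    seed = stream_seed(cfg$seed, "pathways"), ids = ids, feat = cfg$pathway_ids,
    base_sd = 0.6, log_sd = cfg$log_sd_pathway,
    zero_inflation = cfg$zero_inflation_pathway,
    effect = rep(0, cfg$n_pathways), is_d = is_d,
    conf = factors %*% t(loadings),
    coupling = NULL, u = u)

  # metabolites: positive log-normal, no closure
  set.seed(stream_seed(cfg$seed, "metabolites"))
  metab_log <- matrix(stats::rnorm(cfg$n_metabolites, 1, 1), n, cfg$n_metabolites,
                      byrow = TRUE)
  eff_m <- effect_vector(cfg$metabolite_effects, cfg$metab_ids)
  metab_log <- metab_log + outer(as.numeric(is_d), eff_m * log(2))
  noise <- matrix(stats::rnorm(n * cfg$n_metabolites), n, cfg$n_metabolites)
  csp <- coupling_spec(cp, cfg$metab_ids, side = "b")
  if (!is.null(csp))
    for (i in seq_len(nrow(csp))) {
      j <- csp$col[i]
      noise[, j] <- csp$sign[i] * csp$strength[i] * u[, csp$k[i]] +
        sqrt(1 - csp$strength[i]^2) * noise[, j]
    }
  metab <- exp(metab_log + cfg$log_sd * noise)
  dimnames(metab) <- list(ids, cfg$metab_ids)

  design <- cohort_design(ids, group, as.data.frame(covmat))
  lineage <- paste0("k__Bacteria|p__Phylum", (seq_len(cfg$n_taxa) - 1L) %% 4L + 1L,
                    "|s__", cfg$taxa_ids)
  taxa_tab <- abundance_table(taxa, parse_lineages(lineage), "percent")
  truth <- structure(list(
    differential_taxa = cfg$taxa_effects,
    differential_metabolites = cfg$metabolite_effects,
    couplings = cfg$couplings,
    confounders = cov$name[abs(smd_expected) > 0.2],
    smd_expected = smd_expected,
    taxa_confounding = taxa_conf,
    pathway_coupling = cfg$pathway_coupling), class = "truth_sheet")
  structure(list(taxa = taxa_tab,
                 pathways = abundance_table(pathways, scale_tag = "percent"),
                 metabolites = abundance_table(metab, scale_tag = "count"),
                 design = design, truth = truth, config = cfg),
            class = "sim_cohort")
}

effect_vector <- function(effects, feat) {
  v <- rep(0, length(feat))
  names(v) <- feat
  if (!is.null(effects) && nrow(effects)) v[effects$feature] <- effects$log2_fc
  v
}

conf_matrix <- function(conf, feat, z) {
  m <- matrix(0, nrow(z), length(feat), dimnames = list(rownames(z), feat))
  if (!is.null(conf) && nrow(conf))
    for (i in seq_len(nrow(conf)))
      m[, conf$feature[i]] <- m[, conf$feature[i]] +
        conf$strength[i] * z[, conf$covariate[i]]
  m
}

coupling_spec <- function(cp, feat, side) {
  if (is.null(cp) || !nrow(cp)) return(NULL)
  col_id <- if (side == "a") cp$feature_a else cp$feature_b
  keep <- col_id %in% feat
  if (!any(keep)) return(NULL)
  data.frame(col = match(col_id[keep], feat), k = which(keep),
             sign = if (side == "a") rep(1, sum(keep)) else cp$sign[keep],
             strength = cp$strength[keep])
}

# Shared machinery for the two compositional tables: latent log-normal with
# per-feature baselines, additive log-scale terms, zero inflation, closure to
# percent rows. Fully-zero rows are redrawn (zeros only) up to 100 times.
simulate_composition <- function(seed, ids, feat, base_sd, log_sd,
                                 zero_inflation, effect, is_d, conf,
                                 coupling, u) {
  set.seed(seed)
  n <- length(ids)
  p <- length(feat)
  base <- stats::rnorm(p, 0, base_sd)
  L <- matrix(base, n, p, byrow = TRUE)
  L <- L + outer(as.numeric(is_d), effect * log(2))
  if (!is.null(conf)) L <- L + conf
  noise <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(coupling))
    for (i in seq_len(nrow(coupling))) {
      j <- coupling$col[i]
      noise[, j] <- coupling$sign[i] * coupling$strength[i] * u[, coupling$k[i]] +
        sqrt(1 - coupling$strength[i]^2) * noise[, j]
    }
  L <- L + log_sd * noise
  A <- exp(L)
  if (zero_inflation > 0) {
    keep <- matrix(stats::rbinom(n * p, 1, 1 - zero_inflation), n, p)
    for (s in seq_len(n)) {
      tries <- 0
      while (sum(keep[s, ]) == 0) {
        tries <- tries + 1
        if (tries > 100) stop("zero-inflation produced an all-zero sample 100 times")
        keep[s, ] <- stats::rbinom(p, 1, 1 - zero_inflation)
      }
    }
    A <- A * keep
  }
  A <- 100 * A / rowSums(A)
  dimnames(A) <- list(ids, feat)
  A
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d disease / %d control; %d taxa, %d pathways, %d metabolites\n",
              x$config$n_disease, x$config$n_control, x$config$n_taxa,
              x$config$n_pathways, x$config$n_metabolites))
  cat(sprintf("planted: %d taxa effects, %d metabolite effects, %d couplings; confounders: %s\n",
              nrow(x$truth$differential_taxa), nrow(x$truth$differential_metabolites),
              nrow(x$truth$couplings), paste(x$truth$confounders, collapse = ", ")))
  invisible(x)
}

#' Generate a random rooted bifurcating phylogeny
#'
#' Exponential branch lengths; intended as a UniFrac fixture whose leaves can
#' be named after taxa feature ids.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed.
#' @param tip_labels optional character vector of length `n_leaves`.
#' @return an `ape::phylo` rooted tree.
#' @export
generate_tree <- function(n_leaves, seed = 1L, tip_labels = NULL) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  set.seed(stream_seed(seed, "tree"))
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = stats::rexp)
  if (!is.null(tip_labels)) {
    if (length(tip_labels) != n_leaves)
      stop("tip_labels must have length n_leaves")
    tree$tip.label <- tip_labels
  }
  validate_phylogeny(tree)
  tree
}

#' Write all tables of a simulated cohort to a directory
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param tree optional phylogeny to write as `tree.nwk`.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_abundance_table(cohort$taxa, file.path(dir, "taxa.tsv")),
    write_abundance_table(cohort$pathways, file.path(dir, "pathways.tsv")),
    write_abundance_table(cohort$metabolites, file.path(dir, "metabolites.tsv")),
    write_results(as.data.frame(cohort$design), file.path(dir, "design.tsv")),
    write_results(cohort$truth$differential_taxa, file.path(dir, "truth_taxa.tsv")),
    write_results(cohort$truth$differential_metabolites,
                  file.path(dir, "truth_metabolites.tsv")),
    write_results(cohort$truth$couplings, file.path(dir, "truth_couplings.tsv")))
  if (!is.null(tree)) files <- c(files, write_newick(tree, file.path(dir, "tree.nwk")))
  invisible(files)
}
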