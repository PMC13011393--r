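#' Assemble a pipeline configuration
#'
#' Precedence is caller arguments > config file > defaults. The config file
#' is JSON with the same field names as the arguments.
#'
#' @param community,metadata,tree,env input file paths (`tree` and `env`
#'   optional; the corresponding stages are skipped when absent).
#' @param out_dir output directory.
#' @param depth optional rarefaction depth (skipped when `NULL`).
#' @param schemes null schemes to run (`"MODEL_I"`, `"MODEL_II"` or both).
#' @param n_perm permutations for the beta-deviation nulls.
#' @param n_null randomizations for betaNTI / RC_bray.
#' @param bnti_thresh,rc_thresh classification thresholds.
#' @param seed integer master seed.
#' @param config_file optional JSON file supplying any of the above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(community = NULL, metadata = NULL, tree = NULL,
                            env = NULL, out_dir = NULL, depth = NULL,
                            schemes = c("MODEL_I", "MODEL_II"),
                            n_perm = 1000L, n_null = 999L, bnti_thresh = 2,
                            rc_thresh = 0.95, seed = 1L, config_file = NULL) {
  cfg <- list(community = community, metadata = metadata, tree = tree,
              env = env, out_dir = out_dir, depth = depth, schemes = schemes,
              n_perm = n_perm, n_null = n_null, bnti_thresh = bnti_thresh,
              rc_thresh = rc_thresh, seed = seed)
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    supplied <- !vapply(cfg, is.null, TRUE) &
      names(cfg) %in% names(as.list(match.call()))
    for (nm in names(file_cfg))
      if (nm %in% names(cfg) && !supplied[[nm]]) cfg[[nm]] <- file_cfg[[nm]]
  }
  if (is.null(cfg$community) || is.null(cfg$metadata) || is.null(cfg$out_dir))
    stop("'community', 'metadata' and 'out_dir' are required", call. = FALSE)
  if (cfg$bnti_thresh <= 0 || cfg$rc_thresh <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] %-12s %.1fs", format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full inference chain
#'
#' rarefaction (optional) -> per-region alpha/beta/gamma -> null models I/II
#' and beta-deviation -> betaNTI / RC_bray process partition (when a tree is
#' supplied) -> environmental heterogeneity, beta-environment association and
#' db-RDA (when an environmental table is supplied). All stage outputs are
#' TSV; a JSON manifest records every parameter and seed needed to regenerate
#' them.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list()
  t0 <- as.numeric(Sys.time())

  tab <- read_community_table(config$community, config$metadata)
  if (!is.null(config$depth)) {
    tab <- rarefy(tab, config$depth, seed = derive_seed(config$seed, 1L))
    write_community_table(tab, out("rarefied.tsv"))
  }
  stage_log("load", t0)

  results$diversity <- diversity_summary(tab)
  write_tsv(results$diversity, out("diversity_regions.tsv"))
  pairs <- do.call(rbind, lapply(regions(tab), function(r) {
    d <- regional_diversity(tab, r)
    cbind(region = r, d$beta_pairs)
  }))
  write_tsv(pairs, out("diversity_pairs.tsv"))
  stage_log("diversity", t0)

  results$deviation <- deviation_summary(tab, schemes = config$schemes,
                                         n_perm = config$n_perm,
                                         seed = derive_seed(config$seed, 2L))
  write_tsv(results$deviation, out("deviation.tsv"))
  stage_log("deviation", t0)

  if (!is.null(config$tree)) {
    tree <- if (inherits(config$tree, "phylo")) config$tree
            else read_phylogeny(config$tree)
    metrics <- do.call(rbind, lapply(regions(tab), function(r) {
      process_metrics(tab, r, tree, n_null = config$n_null,
                      seed = derive_seed(config$seed, 3L + match(r, regions(tab))),
                      bnti_thresh = config$bnti_thresh,
                      rc_thresh = config$rc_thresh)
    }))
    results$metrics <- metrics
    results$partition <- partition_processes(metrics)
    write_tsv(metrics, out("partition_pairs.tsv"))
    write_tsv(results$partition, out("partition_fractions.tsv"))
    stage_log("partition", t0)
  }

  if (!is.null(config$env)) {
    env <- if (is.matrix(config$env)) config$env else read_env_table(config$env)
    env <- env[colnames(tab$counts), , drop = FALSE]
    env_z <- standardize_env(env)
    ed <- env_distance(env_z)
    em <- as.matrix(ed)
    lt <- lower.tri(em)
    idx <- which(lt, arr.ind = TRUE)
    write_tsv(data.frame(sample_i = rownames(em)[idx[, 2L]],
                         sample_j = rownames(em)[idx[, 1L]],
                         env_distance = em[idx]),
              out("env_heterogeneity.tsv"))
    bc <- pairwise_bray(tab$counts)
    results$beta_env <- beta_env_association(bc, em, n_perm = config$n_perm,
                                             seed = derive_seed(config$seed, 50L))
    results$dbrda <- dbrda(bc, env_z, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 51L))
    write_tsv(data.frame(statistic = c("total_inertia", "constrained_inertia",
                                       "r_squared", "global_F", "global_p",
                                       "assoc_slope", "assoc_r", "assoc_p"),
                         value = c(results$dbrda$total_inertia,
                                   results$dbrda$constrained_inertia,
                                   results$dbrda$r_squared,
                                   results$dbrda$global_F,
                                   results$dbrda$global_p,
                                   results$beta_env$slope,
                                   results$beta_env$r,
                                   results$beta_env$p_value)),
              out("dbrda_summary.tsv"))
    write_tsv(results$dbrda$terms, out("dbrda_terms.tsv"))
    stage_log("environment", t0)
  }

  manifest <- list(package = "betanull",
                   version = as.character(utils::packageVersion("betanull")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(config))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(results)
}
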