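# Orchestration of the headline workflow: cluster each water type,
# fit the mixing model per cluster, run the screening diagnostics, and
# write a consolidated, auditable set of CSV/JSON outputs.

#' Run the full cluster-then-mix workflow
#'
#' Per water type the samples are Ward-clustered on the configured
#' tracers and cut at the configured k; per cluster the Bayesian
#' mixing model is fitted and summarized as a contribution-rate table;
#' the denitrification/mixing correlation screen runs per region and
#' per cluster; the nitrification window classification and exceedance
#' flags run per sample.  All outputs plus a run manifest are written
#' to `out_dir`.
#'
#' @param samples Canonical sample data.frame or path to a samples CSV.
#' @param sources Long-form source data.frame or path to a sources CSV.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if missing).
#' @param d18O_O2 Dissolved-oxygen d18O for the nitrification window
#'   (per mil).
#' @param write_draws Also write the retained posterior draws
#'   (`draws.csv`, with chain and iteration columns)?  Off by default.
#' @return Invisibly, a list with `assignments`, `gvf`,
#'   `contributions`, `diagnostics`, `nitrification`, `exceedance`,
#'   `posteriors`, `manifest`.  The manifest's `ok` field is TRUE iff
#'   every stage completed and every fit converged.
#' @export
run_cluster_then_mix <- function(samples, sources, config = analysis_config(),
                                 out_dir, d18O_O2 = 23.5,
                                 write_draws = FALSE) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(sources)) sources <- read_sources(sources)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$rng_seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = character(), warnings = character(),
                   outputs = character(), ok = FALSE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  on.exit(write_manifest(), add = TRUE)

  issues <- validate_dataset(samples, sources, config)
  hard <- issues[issues$code %in% c("duplicate_id", "missing_tracer_column",
                                    "source_missing_tracer", "negative_sd",
                                    "negative_frac_sd"), , drop = FALSE]
  if (nrow(hard)) {
    manifest$stages <- c(manifest$stages, "validate:FAILED")
    stop("dataset validation failed:\n  ",
         paste(hard$message, collapse = "\n  "))
  }
  manifest$stages <- c(manifest$stages, "validate")

  # --- clustering -----------------------------------------------------
  clusters <- cluster_water_samples(samples, config)
  assignments <- do.call(rbind, lapply(clusters, function(cr) {
    data.frame(sample_id = names(cr$assignments),
               water_type = cr$water_type,
               cluster_label = paste0(cr$water_type, cr$assignments),
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  gvf <- do.call(rbind, lapply(clusters, function(cr) {
    rbind(data.frame(scope = cr$water_type, label = "partition",
                     gvf = cr$partition_gvf, stringsAsFactors = FALSE),
          data.frame(scope = cr$water_type,
                     label = names(cr$per_group_gvf),
                     gvf = unname(cr$per_group_gvf), stringsAsFactors = FALSE))
  }))
  rownames(gvf) <- NULL
  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(gvf, file.path(out_dir, "gvf.csv"), row.names = FALSE)
  for (cr in clusters) {
    jsonlite::write_json(
      list(water_type = cr$water_type, n_leaves = cr$tree$n_leaves,
           labels = cr$tree$labels, merges = cr$tree$merges),
      file.path(out_dir, paste0("linkage_", cr$water_type, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$stages <- c(manifest$stages, "cluster")

  # --- mixing per cluster --------------------------------------------
  posteriors <- list(); contrib <- list(); draws_out <- list()
  all_converged <- TRUE
  for (cr in clusters) {
    for (lab in sort(unique(cr$assignments))) {
      glab <- paste0(cr$water_type, lab)
      ids <- names(cr$assignments)[cr$assignments == lab]
      sub <- samples[samples$sample_id %in% ids, , drop = FALSE]
      mc <- config$mcmc
      # offset the chain seed per group so groups are not coupled
      mc$rng_seed <- (mc$rng_seed + 7919L * length(posteriors)) %%
        .Machine$integer.max
      post <- fit_mixing_model(sub, sources, mcmc = mc,
                               tracers = config$tracers,
                               group_label = glab)
      posteriors[[glab]] <- post
      if (!post$converged) {
        all_converged <- FALSE
        manifest$warnings <- c(manifest$warnings,
                               paste0("Rhat above threshold for ", glab))
      }
      contrib[[glab]] <- summarize_posterior(post)
      if (write_draws) {
        draws_out[[glab]] <- data.frame(
          group = glab, chain = post$chain,
          iteration = seq_along(post$chain),
          post$draws_P, post$draws_sigma, check.names = FALSE)
      }
    }
  }
  contributions <- do.call(rbind, contrib); rownames(contributions) <- NULL
  utils::write.csv(contributions, file.path(out_dir, "contributions.csv"),
                   row.names = FALSE)
  if (write_draws) {
    utils::write.csv(do.call(rbind, draws_out),
                     file.path(out_dir, "draws.csv"), row.names = FALSE)
  }
  diag_json <- lapply(posteriors, function(p) {
    list(rhat = as.list(p$rhat[!is.na(p$rhat)]),
         accept_rate = p$accept_rate, converged = p$converged)
  })
  jsonlite::write_json(diag_json, file.path(out_dir, "mcmc_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages <- c(manifest$stages, "mix")

  # --- screening diagnostics -----------------------------------------
  scopes <- c(
    split(samples, samples$region),
    split(samples, assignments$cluster_label[match(samples$sample_id,
                                                   assignments$sample_id)])
  )
  diagnostics <- do.call(rbind, lapply(names(scopes), function(sc) {
    denitrification_assessment(scopes[[sc]], alpha = config$alpha_denit,
                               scope = sc)
  }))
  rownames(diagnostics) <- NULL
  utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)

  h2o <- samples$d18O_H2O[is.finite(samples$d18O_H2O)]
  if (length(h2o) >= 1) {
    win <- nitrification_o18_range(min(h2o), max(h2o), d18O_O2 = d18O_O2)
    nitr <- data.frame(sample_id = samples$sample_id,
                       status = classify_nitrification(samples, win),
                       lo = win$lo, hi = win$hi, stringsAsFactors = FALSE)
    utils::write.csv(nitr, file.path(out_dir, "nitrification.csv"),
                     row.names = FALSE)
  } else {
    nitr <- NULL
    manifest$warnings <- c(manifest$warnings,
                           "no d18O_H2O values: nitrification window skipped")
  }
  exc <- exceedance_flags(samples, who_no3 = config$thresholds$who_no3,
                          class_v_tn = config$thresholds$class_v_tn)
  utils::write.csv(exc, file.path(out_dir, "exceedance.csv"),
                   row.names = FALSE)
  manifest$stages <- c(manifest$stages, "diagnose")

  manifest$outputs <- list.files(out_dir)
  manifest$ok <- all_converged
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest()

  invisible(list(assignments = assignments, gvf = gvf,
                 contributions = contributions, diagnostics = diagnostics,
                 nitrification = nitr, exceedance = exc,
                 posteriors = posteriors, clusters = clusters,
                 manifest = manifest))
}

#' Available built-in synthetic scenarios
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() c("basin-demo", "rayleigh-demo")

#' Simulate a scenario and write its files
#'
#' Writes `samples.csv`, `sources.csv` and `truth.json` (true
#' proportions per group, denitrification parameters, per-sample
#' fraction remaining, and the seed) to `out_dir`, in the formats the
#' rest of the pipeline reads.
#'
#' @param scenario A name from [list_scenarios()], or a
#'   `"synthetic_spec"` object.
#' @param seed Integer seed (ignored when a spec carries its own).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the generated `"synthetic_dataset"`.
#' @export
simulate_scenario <- function(scenario = "basin-demo", seed = 1L, out_dir) {
  if (inherits(scenario, "synthetic_spec")) {
    ds <- generate_mixture_samples(scenario)
    sources <- scenario$sources
  } else if (identical(scenario, "basin-demo")) {
    ds <- generate_basin_scenario(seed)
    sources <- basin_source_profiles()
  } else if (identical(scenario, "rayleigh-demo")) {
    ds <- generate_rayleigh_demo(seed)
    sources <- ds$truth$spec$sources
  } else {
    stop("unknown scenario '", scenario, "'; available: ",
         paste(list_scenarios(), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(ds$samples, file.path(out_dir, "samples.csv"))
  write_sources(sources, file.path(out_dir, "sources.csv"))
  denit <- ds$truth$denitrification
  jsonlite::write_json(list(
    seed = seed,
    true_p = lapply(ds$truth$true_p, as.list),
    denitrification = if (is.null(denit)) NULL else
      denit[c("eps", "f_range", "n_o_ratio", "sample_ids")],
    f = stats::setNames(as.list(ds$truth$per_sample$f),
                        ds$truth$per_sample$sample_id)
  ), file.path(out_dir, "truth.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}
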