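# Canonical sample-table columns.  Tracers are per-mil (d15N vs air-N2,
# d18O vs VSMOW); concentrations mg/L of the stated species; cond uS/cm.
SAMPLE_COLUMNS <- c(
  "sample_id", "water_type", "region",
  "d15N_NO3", "d18O_NO3",
  "no3", "tn", "nh4", "cond", "d18O_H2O"
)
SAMPLE_REQUIRED <- c("sample_id", "water_type", "d15N_NO3", "d18O_NO3")
SAMPLE_NUMERIC <- c("d15N_NO3", "d18O_NO3", "no3", "tn", "nh4", "cond", "d18O_H2O")

#' Default tracer set
#'
#' The two nitrate isotope tracers used throughout the pipeline, in the
#' fixed order used for clustering features and mixing-model dimensions.
#' @return Character vector of tracer column names.
#' @export
default_tracers <- function() c("d15N_NO3", "d18O_NO3")

#' Analysis configuration
#'
#' Bundles the knobs shared by the clustering, mixing and diagnostics
#' stages.  The tracer order fixed here is used consistently everywhere
#' (clustering feature order, mixing-model dimension order) so that the
#' two isotopes can never be silently permuted.
#'
#' @param tracers Ordered character vector of tracer column names.
#' @param k_surface,k_ground Number of clusters per water type (default 2).
#' @param standardize_features Standardize tracers to unit variance before
#'   clustering?  Off by default: both tracers share the per-mil scale.
#' @param who_no3 Drinking-water nitrate guideline in mg/L (default 50,
#'   the WHO maximum for nitrate in drinking water).
#' @param class_v_tn Total-nitrogen threshold in mg/L used for the
#'   surface-water class V exceedance flag.  The shipped default (2.0)
#'   is an external-standard constant (GB3838-2002) supplied for
#'   convenience; analyses citing the standard should set it explicitly.
#' @param alpha_denit Two-tailed significance level for the
#'   denitrification/mixing correlation screen (default 0.01).
#' @param mcmc An [mcmc_config()] list.
#' @param rng_seed Integer seed for every stochastic stage.
#' @return A list of class `"nitra_config"`.
#' @export
analysis_config <- function(tracers = default_tracers(),
                            k_surface = 2L, k_ground = 2L,
                            standardize_features = FALSE,
                            who_no3 = 50, class_v_tn = 2.0,
                            alpha_denit = 0.01,
                            mcmc = mcmc_config(),
                            rng_seed = 1L) {
  stopifnot(length(tracers) >= 1, k_surface >= 1, k_ground >= 1,
            who_no3 > 0, class_v_tn > 0, alpha_denit > 0, alpha_denit < 1)
  structure(list(
    tracers = tracers,
    k_surface = as.integer(k_surface), k_ground = as.integer(k_ground),
    standardize_features = isTRUE(standardize_features),
    thresholds = list(who_no3 = who_no3, class_v_tn = class_v_tn),
    alpha_denit = alpha_denit,
    mcmc = mcmc,
    rng_seed = as.integer(rng_seed)
  ), class = "nitra_config")
}

#' Read water-sample records from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row, `"."` decimal
#' separator and the empty string for missing values.  Required columns:
#' `sample_id`, `water_type`, `d15N_NO3`, `d18O_NO3`; optional columns:
#' `region`, `no3`, `tn`, `nh4`, `cond`, `d18O_H2O`.  Optional fields
#' absent from the file (or empty on a row) come back as `NA`, never as
#' a silent zero.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(sample_id = "ID", d15N_NO3 = "d15N")`.
#' @return A data.frame with the canonical columns, one row per sample,
#'   in file order.
#' @export
read_samples <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  missing_req <- setdiff(SAMPLE_REQUIRED, names(raw))
  if (length(missing_req)) {
    stop("sample file is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(raw$sample_id),
                    stringsAsFactors = FALSE)
  out$water_type <- as.character(raw$water_type)
  bad_wt <- !out$water_type %in% c("surface", "ground")
  if (any(bad_wt)) {
    stop("water_type must be 'surface' or 'ground'; offending row(s): ",
         paste(which(bad_wt), collapse = ", "))
  }
  out$region <- if ("region" %in% names(raw)) as.character(raw$region) else NA_character_
  for (col in SAMPLE_NUMERIC) {
    if (col %in% names(raw)) {
      v <- raw[[col]]
      if (is.character(v)) {
        conv <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(conv))
        if (length(bad)) {
          stop("non-numeric value in column '", col, "' at data row(s): ",
               paste(bad, collapse = ", "))
        }
        v <- conv
      }
      out[[col]] <- as.numeric(v)
    } else {
      out[[col]] <- NA_real_
    }
  }
  if (any(!is.na(out$no3) & out$no3 < 0)) {
    stop("negative no3 concentration(s) in ", path)
  }
  out[SAMPLE_COLUMNS]
}

#' Write water-sample records to CSV
#'
#' Inverse of [read_samples()]: writes the canonical schema so that a
#' read/write round trip is the identity field for field.
#'
#' @param samples Sample data.frame in the canonical schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples[intersect(SAMPLE_COLUMNS, names(samples))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read nitrate source signatures from CSV
#'
#' Two layouts are accepted.  Long form has columns
#' `source_id, tracer, mean, sd` and optionally `frac_mean, frac_sd`,
#' one row per (source, tracer).  Wide form has one row per source with
#' columns `source_id`, `mean_<tracer>`, `sd_<tracer>` and optionally
#' `frac_mean_<tracer>`, `frac_sd_<tracer>` for each tracer.  Absent
#' fractionation columns default to mean 0 and sd 0 (conservative
#' mixing); source standard deviations are mandatory.
#'
#' @param path Path to a CSV file.
#' @return A long-form data.frame with columns
#'   `source_id, tracer, mean, sd, frac_mean, frac_sd`.
#' @export
read_sources <- function(path) {
  if (!file.exists(path)) stop("source file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = "")
  if (!"source_id" %in% names(raw)) stop("source file needs a source_id column")
  if ("tracer" %in% names(raw)) {
    if (!all(c("mean", "sd") %in% names(raw))) {
      stop("long-form source file needs 'mean' and 'sd' columns ",
           "(source isotope uncertainty is mandatory)")
    }
    out <- data.frame(source_id = as.character(raw$source_id),
                      tracer = as.character(raw$tracer),
                      mean = as.numeric(raw$mean),
                      sd = as.numeric(raw$sd),
                      stringsAsFactors = FALSE)
    out$frac_mean <- if ("frac_mean" %in% names(raw)) as.numeric(raw$frac_mean) else 0
    out$frac_sd <- if ("frac_sd" %in% names(raw)) as.numeric(raw$frac_sd) else 0
  } else {
    mean_cols <- grep("^mean_", names(raw), value = TRUE)
    if (!length(mean_cols)) {
      stop("source file is neither long form (tracer column) nor wide ",
           "form (mean_<tracer> columns)")
    }
    tracers <- sub("^mean_", "", mean_cols)
    miss_sd <- tracers[!paste0("sd_", tracers) %in% names(raw)]
    if (length(miss_sd)) {
      stop("wide-form source file lacks sd_ column(s) for: ",
           paste(miss_sd, collapse = ", "),
           " (source isotope uncertainty is mandatory)")
    }
    out <- do.call(rbind, lapply(tracers, function(tr) {
      data.frame(
        source_id = as.character(raw$source_id), tracer = tr,
        mean = as.numeric(raw[[paste0("mean_", tr)]]),
        sd = as.numeric(raw[[paste0("sd_", tr)]]),
        frac_mean = if (paste0("frac_mean_", tr) %in% names(raw))
          as.numeric(raw[[paste0("frac_mean_", tr)]]) else 0,
        frac_sd = if (paste0("frac_sd_", tr) %in% names(raw))
          as.numeric(raw[[paste0("frac_sd_", tr)]]) else 0,
        stringsAsFactors = FALSE)
    }))
  }
  out$frac_mean[is.na(out$frac_mean)] <- 0
  out$frac_sd[is.na(out$frac_sd)] <- 0
  if (any(is.na(out$mean)) || any(is.na(out$sd))) {
    stop("source means and sds must all be present and numeric")
  }
  if (any(out$sd < 0) || any(out$frac_sd < 0)) {
    stop("source sd and frac_sd must be non-negative")
  }
  rownames(out) <- NULL
  out[order(match(out$source_id, unique(out$source_id))), , drop = FALSE]
}

#' Write source signatures to CSV (long form)
#' @param sources Long-form source data.frame (see [read_sources()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sources <- function(sources, path) {
  utils::write.csv(sources, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a samples + sources dataset against a configuration
#'
#' A reporting operation: it never throws, it lists every violation it
#' finds (duplicate sample ids, tracer coverage gaps in the source
#' table, negative dispersions, unusable tracer values).  An empty
#' report means the dataset can run through clustering and mixing
#' without shape errors.
#'
#' @param samples Canonical sample data.frame.
#' @param sources Long-form source data.frame.
#' @param config An [analysis_config()].
#' @return A data.frame with columns `code` and `message`, zero rows if
#'   the dataset is clean.
#' @export
validate_dataset <- function(samples, sources, config = analysis_config()) {
  issues <- list()
  add <- function(code, message) {
    issues[[length(issues) + 1L]] <<- data.frame(code = code, message = message,
                                                 stringsAsFactors = FALSE)
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  for (id in dup) add("duplicate_id", paste0("duplicated sample_id: ", id))
  for (tr in config$tracers) {
    if (!tr %in% names(samples)) {
      add("missing_tracer_column", paste0("samples lack tracer column: ", tr))
      next
    }
    n_bad <- sum(!is.finite(samples[[tr]]))
    if (n_bad > 0) {
      add("missing_tracer_values",
          paste0(n_bad, " sample(s) have missing/non-finite ", tr,
                 "; they will be excluded from clustering and mixing"))
    }
  }
  for (sid in unique(sources$source_id)) {
    have <- sources$tracer[sources$source_id == sid]
    for (tr in setdiff(config$tracers, have)) {
      add("source_missing_tracer",
          paste0("source ", sid, " has no signature for tracer ", tr))
    }
  }
  if (any(sources$sd < 0)) add("negative_sd", "negative source sd")
  if (any(sources$frac_sd < 0)) add("negative_frac_sd", "negative fractionation sd")
  if (any(!is.na(samples$no3) & samples$no3 < 0)) {
    add("negative_no3", "negative nitrate concentration")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
}
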