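# Tab-delimited readers/writers and the end-to-end driver. TSV (UTF-8, '.'
# decimal) is the canonical tabular dialect throughout.

#' Read a feature x sample intensity matrix from TSV
#'
#' Expects feature ids in the first column and sample ids in the header.
#' Empty cells are read as zero (undetected) and counted; duplicate ids or
#' non-numeric cells are errors naming the offender.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with feature rownames and sample colnames; the
#'   number of empty cells read as zero is attached as attribute
#'   `"n_empty_as_zero"`.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix TSV needs id column + samples",
                          call. = FALSE)
  feats <- df[[1L]]
  if (anyDuplicated(feats)) {
    stop("duplicated feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  }
  samp <- colnames(df)[-1L]
  if (anyDuplicated(samp)) {
    stop("duplicated sample id(s): ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  n_empty <- sum(vals == "" | is.na(vals))
  vals[vals == "" | is.na(vals)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", feats[bad[1L]], "', column '",
         samp[bad[2L]], "'", call. = FALSE)
  }
  dimnames(num) <- list(feats, samp)
  attr(num, "n_empty_as_zero") <- n_empty
  num
}

#' Write a feature x sample matrix to TSV
#'
#' Inverse of [read_intensity_tsv()]: the round trip preserves ids and
#' values.
#'
#' @param values Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name of the feature-id column; default `"feature_id"`.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(values, path, id_col = "feature_id") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis end to end on a seeded synthetic study
#'
#' Drives every stage with one configuration: simulates a lipidomics
#' dataset and tumor growth curves, writes the inputs, fits the
#' differential lipidomics pipeline ([lipid_diff()]), computes growth
#' metrics ([auc_tgi()], [endpoint_ttest()]), and writes all result TSVs, a
#' provenance JSON, and a plain-text summary into `out_dir`. All randomness
#' flows from the single configured seed, so a rerun with the same config
#' produces byte-identical result TSVs.
#'
#' @param config A named list (or path to a YAML file parsed into one) with
#'   optional entries `seed` (default 1), `sim` (arguments to
#'   [sim_config()]), `lipid` (`presence_fraction`, `presence_scope`,
#'   `offset_rule`), and `growth` (`n_per_arm`, `t_max_weeks`,
#'   `growth_rate_control`, `growth_rate_treated`, `noise_sd`, `n_boot`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `lipid_diff` fit, the `tgi_result`,
#'   and the paths written.
#' @export
run_all <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "sim", "lipid", "growth")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0L) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  lipid_cfg <- config$lipid
  if (!is.null(lipid_cfg$presence_fraction) &&
      (lipid_cfg$presence_fraction <= 0 || lipid_cfg$presence_fraction > 1)) {
    stop("config field 'lipid$presence_fraction' must lie in (0, 1]",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim_args <- config$sim
  sim_args$seed <- seed
  sim <- simulate_lipidomics(do.call(sim_config, as.list(sim_args)))

  growth_cfg <- config$growth
  g_args <- list(
    n_per_arm = growth_cfg$n_per_arm %||% 5L,
    t_max_weeks = growth_cfg$t_max_weeks %||% 5L,
    growth_rate_control = growth_cfg$growth_rate_control %||% 0.3,
    growth_rate_treated = growth_cfg$growth_rate_treated %||% 0.1,
    noise_sd = growth_cfg$noise_sd %||% 0.1,
    seed = seed
  )
  growth <- do.call(simulate_growth, g_args)

  paths <- list(
    matrix = file.path(out_dir, "intensity_matrix.tsv"),
    metadata = file.path(out_dir, "sample_metadata.tsv"),
    class_map = file.path(out_dir, "class_map.tsv"),
    truth = file.path(out_dir, "truth.json"),
    growth = file.path(out_dir, "growth.tsv"),
    lipid_results = file.path(out_dir, "per_lipid_results.tsv"),
    class_results = file.path(out_dir, "per_class_results.tsv"),
    growth_results = file.path(out_dir, "growth_results.tsv"),
    provenance = file.path(out_dir, "provenance.json"),
    summary = file.path(out_dir, "summary.txt")
  )
  write_intensity_tsv(sim$values, paths$matrix)
  write_tsv(sim$metadata, paths$metadata)
  write_tsv(sim$class_map, paths$class_map)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  write_tsv(as.data.frame(growth), paths$growth)

  fit <- lipid_diff(
    sim,
    presence_fraction = lipid_cfg$presence_fraction %||% 2 / 3,
    presence_scope = lipid_cfg$presence_scope %||% "per_patient",
    offset_rule = lipid_cfg$offset_rule %||% "multiplicative"
  )
  lt <- fit$lipid_tests
  lt$class <- stats::setNames(sim$class_map$class,
                              sim$class_map$feature_id)[lt$feature]
  write_tsv(lt[, c("feature", "class", "n", "mean_fc", "t", "df", "p",
                   "flag")], paths$lipid_results)
  write_tsv(as.data.frame(fit$class_results), paths$class_results)

  tgi <- auc_tgi(growth, n_boot = growth_cfg$n_boot %||% 2000L,
                 seed = seed)
  endpoint <- {
    last <- max(growth$week)
    v <- growth$volume_mm3[growth$week == last]
    arm <- growth$arm[growth$week == last]
    endpoint_ttest(v[arm == "control"], v[arm == "treated"])
  }
  write_tsv(data.frame(
    metric = c("tgi", "tgi_ci_lower", "tgi_ci_upper", "aauc_control",
               "aauc_treated", "endpoint_t", "endpoint_df", "endpoint_p"),
    value = c(tgi$tgi, tgi$ci[["lower"]], tgi$ci[["upper"]],
              tgi$aauc_control, tgi$aauc_treated, endpoint$t, endpoint$df,
              endpoint$p_value)
  ), paths$growth_results)

  prov <- list(
    package_version = as.character(utils::packageVersion("lipidsign")),
    seed = seed,
    config = config,
    stages = list(
      simulate = list(n_features = nrow(sim$values),
                      n_samples = ncol(sim$values)),
      lipid_diff = fit$provenance[c("log_offset", "offset_rule",
                                    "presence_fraction", "presence_scope",
                                    "n_features_input",
                                    "n_features_retained",
                                    "normalization")],
      growth = list(n_animals = length(unique(growth$animal_id)),
                    n_boot = tgi$n_boot)
    ),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA)

  summary_lines <- c(
    "lipidsign run-all summary",
    sprintf("seed: %d", seed),
    sprintf("lipids retained: %d of %d",
            fit$provenance$n_features_retained,
            fit$provenance$n_features_input),
    sprintf("classes with binomial p < 0.05: %d",
            sum(fit$class_results$p_value < 0.05, na.rm = TRUE)),
    sprintf("TGI: %s", format(tgi$tgi, digits = 6)),
    sprintf("endpoint t-test p: %s", format(endpoint$p_value, digits = 6))
  )
  writeLines(summary_lines, paths$summary)
  invisible(list(fit = fit, tgi = tgi, endpoint = endpoint, paths = paths))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
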