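# Feature x sample intensity container with explicit processing state.

#' Construct an intensity matrix with sample metadata
#'
#' The container used throughout the lipidomics pipeline: a nonnegative
#' features x samples matrix (zero = undetected) plus per-sample metadata
#' (patient, arm). The processing state is tracked explicitly and may only
#' advance raw -> normalized -> log; the detection mask is frozen from the
#' raw values so later stages can still apply presence rules.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Raw values must be
#'   nonnegative.
#' @param metadata Data frame with columns `sample_id`, `patient`, `arm`
#'   (`"control"`/`"treated"`); one row per column of `values`.
#' @param state One of `"raw"`, `"normalized"`, `"log"`.
#' @param detected Optional logical matrix marking detected cells; defaults
#'   to `values > 0` (only valid for raw/normalized input).
#' @return Object of class `"intensity_matrix"`.
#' @export
intensity_matrix <- function(values, metadata,
                             state = c("raw", "normalized", "log"),
                             detected = NULL) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(metadata))
  req <- c("sample_id", "patient", "arm")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0L) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids", call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  if (anyNA(metadata$sample_id)) {
    stop("metadata is missing rows for some samples in the matrix",
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(metadata$arm), c("control", "treated"))
  if (length(bad_arm) > 0L) {
    stop("arm must be 'control' or 'treated'; found: ",
         paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  if (state != "log" && any(values < 0)) {
    stop("raw/normalized intensities must be nonnegative", call. = FALSE)
  }
  if (is.null(detected)) {
    if (state == "log") {
      stop("a detection mask is required when constructing from log values",
           call. = FALSE)
    }
    detected <- values > 0
  }
  stopifnot(is.logical(detected), identical(dim(detected), dim(values)))
  rownames(metadata) <- NULL
  structure(
    list(values = values, samples = metadata, state = state,
         detected = detected, provenance = list()),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Intensity matrix: %d features x %d samples [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  patients: %d; arms: %d control / %d treated\n",
              length(unique(x$samples$patient)),
              sum(x$samples$arm == "control"),
              sum(x$samples$arm == "treated")))
  cat(sprintf("  undetected cells: %d of %d\n",
              sum(!x$detected), length(x$detected)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Normalize each sample by its total intensity
#'
#' Divides each sample (column) by its summed intensity, so every sample's
#' values add to one. Input must be in the raw state.
#'
#' @param m An `intensity_matrix` with `state == "raw"`.
#' @return The matrix in the `"normalized"` state.
#' @export
normalize_total <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") {
    stop("normalize_total expects state 'raw', got '", m$state, "'",
         call. = FALSE)
  }
  totals <- colSums(m$values)
  bad <- which(totals <= 0)
  if (length(bad) > 0L) {
    stop("sample(s) with nonpositive total intensity: ",
         paste(colnames(m$values)[bad], collapse = ", "), call. = FALSE)
  }
  m$values <- sweep(m$values, 2L, totals, "/")
  m$state <- "normalized"
  m$provenance$sample_totals <- totals
  m
}

#' Offset log-transform of a normalized intensity matrix
#'
#' Adds a small positive offset before taking natural logs so undetected
#' (zero) cells stay finite. Under the default `"multiplicative"` rule the
#' offset is three orders of magnitude below the smallest strictly positive
#' value in the matrix (delta = min positive x 1e-3); the alternative
#' `"subtractive"` rule (delta = min positive - 1e-3) is provided but
#' errors when it would be nonpositive, which is typical after
#' total-intensity normalization.
#'
#' @param m An `intensity_matrix` with `state == "normalized"` (raw input is
#'   accepted with a warning, for matrices normalized upstream).
#' @param offset_rule `"multiplicative"` (default) or `"subtractive"`.
#' @return The matrix in the `"log"` state; the offset used is recorded in
#'   `$provenance$log_offset`.
#' @export
log_transform <- function(m, offset_rule = c("multiplicative",
                                             "subtractive")) {
  stopifnot(inherits(m, "intensity_matrix"))
  offset_rule <- match.arg(offset_rule)
  if (m$state == "log") {
    stop("matrix is already log-transformed", call. = FALSE)
  }
  pos <- m$values[m$values > 0]
  if (length(pos) == 0L) {
    stop("matrix has no positive value; cannot choose a log offset",
         call. = FALSE)
  }
  minpos <- min(pos)
  delta <- switch(offset_rule,
                  multiplicative = minpos * 1e-3,
                  subtractive = minpos - 1e-3)
  if (delta <= 0) {
    stop("subtractive offset rule gives a nonpositive offset (",
         format(delta), "); use the multiplicative rule", call. = FALSE)
  }
  m$values <- log(m$values + delta)
  m$state <- "log"
  m$provenance$log_offset <- delta
  m$provenance$offset_rule <- offset_rule
  m
}

#' Presence filter: keep features detected in enough samples of one arm
#'
#' Retains features whose detection fraction (raw value > 0, via the frozen
#' detection mask) is at least `fraction` in the control samples OR in the
#' treated samples. With `scope = "per_patient"` (default) the rule must
#' hold within every patient, matching the per-patient centering downstream;
#' `scope = "pooled"` evaluates it across all samples of each arm.
#'
#' @param m An `intensity_matrix` (any state).
#' @param fraction Required detection fraction in `(0, 1]`; default `2/3`.
#'   The comparison is `>=`, so a lipid in exactly 2 of 3 samples passes.
#' @param scope `"per_patient"` or `"pooled"`.
#' @return The matrix restricted to retained features; dropped ids are
#'   recorded in `$provenance$presence_dropped`.
#' @export
presence_filter <- function(m, fraction = 2 / 3,
                            scope = c("per_patient", "pooled")) {
  stopifnot(inherits(m, "intensity_matrix"))
  scope <- match.arg(scope)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  det <- m$detected
  arm <- m$samples$arm
  pass_group <- function(cols) {
    ctrl <- cols[arm[cols] == "control"]
    trt <- cols[arm[cols] == "treated"]
    frac <- function(ix) {
      if (length(ix) == 0L) return(rep(0, nrow(det)))
      rowMeans(det[, ix, drop = FALSE])
    }
    frac(ctrl) >= fraction | frac(trt) >= fraction
  }
  if (scope == "pooled") {
    keep <- pass_group(seq_len(ncol(det)))
  } else {
    keep <- rep(TRUE, nrow(det))
    for (p in unique(m$samples$patient)) {
      keep <- keep & pass_group(which(m$samples$patient == p))
    }
  }
  dropped <- rownames(m$values)[!keep]
  m$values <- m$values[keep, , drop = FALSE]
  m$detected <- det[keep, , drop = FALSE]
  m$provenance$presence_dropped <- dropped
  m$provenance$presence_fraction <- fraction
  m$provenance$presence_scope <- scope
  m
}

#' Cross-sample recurrence filter for assigned features
#'
#' Stand-in reproducibility filter applied before quantitative analysis:
#' retains features whose assignment recurs in at least `min_fraction` of
#' the samples of at least one arm. Input is the per-sample sets of
#' assigned feature ids (e.g. from [assign_peaks()] applied to each
#' sample's raw peak list).
#'
#' @param features_by_sample Named list (one element per sample) of
#'   character vectors of assigned feature ids.
#' @param arm Character vector of arms (`"control"`/`"treated"`), parallel
#'   to `features_by_sample`.
#' @param min_fraction Required recurrence fraction in `(0, 1]`;
#'   default 0.5.
#' @return Character vector of retained feature ids.
#' @export
hpd_filter <- function(features_by_sample, arm, min_fraction = 0.5) {
  stopifnot(is.list(features_by_sample),
            length(features_by_sample) == length(arm),
            length(features_by_sample) >= 1L)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  arm <- as.character(arm)
  all_feats <- unique(unlist(features_by_sample))
  if (length(all_feats) == 0L) return(character(0))
  keep <- logical(length(all_feats))
  for (a in unique(arm)) {
    ix <- which(arm == a)
    counts <- table(factor(unlist(lapply(features_by_sample[ix], unique)),
                           levels = all_feats))
    keep <- keep | (as.numeric(counts) / length(ix) >= min_fraction)
  }
  all_feats[keep]
}
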