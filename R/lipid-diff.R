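# Differential lipidomics: patient-centered log fold-changes, per-lipid
# one-sample t-tests, and the class-level binomial sign test with its
# log-ratio effect statistic.

#' Center log intensities on each patient's control mean
#'
#' For every patient and feature, subtracts that patient's control-sample
#' mean log intensity from all of the patient's samples. Centered treated
#' values are log fold-changes of treated versus control for that patient;
#' centered control values average zero by construction.
#'
#' @param m An `intensity_matrix` with `state == "log"`; every patient must
#'   have at least one control sample.
#' @return Object of class `"fold_change_table"`: a list with `centered`
#'   (features x samples matrix), `samples` (metadata), `mean_fc` (per
#'   feature, mean over all treated samples), `n_treated`, and the
#'   accumulated provenance.
#' @export
center_on_controls <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "log") {
    stop("center_on_controls expects state 'log', got '", m$state, "'",
         call. = FALSE)
  }
  centered <- m$values
  for (p in unique(m$samples$patient)) {
    cols <- which(m$samples$patient == p)
    ctrl <- cols[m$samples$arm[cols] == "control"]
    if (length(ctrl) == 0L) {
      stop("patient '", p, "' has no control samples", call. = FALSE)
    }
    ctrl_mean <- rowMeans(m$values[, ctrl, drop = FALSE])
    centered[, cols] <- m$values[, cols, drop = FALSE] - ctrl_mean
  }
  treated <- which(m$samples$arm == "treated")
  mean_fc <- rowMeans(centered[, treated, drop = FALSE])
  structure(
    list(centered = centered, samples = m$samples, mean_fc = mean_fc,
         n_treated = length(treated), provenance = m$provenance),
    class = "fold_change_table"
  )
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("Fold-change table: %d features, %d samples (%d treated)\n",
              nrow(x$centered), ncol(x$centered), x$n_treated))
  invisible(x)
}

#' Per-lipid one-sample t-tests of treated log fold-changes against zero
#'
#' For each feature, tests the treated-sample centered log intensities
#' (log fold-changes versus the patient control mean) against zero with a
#' two-sided one-sample t-test. Features with fewer than two treated values
#' are excluded with a reason code; zero-variance features are flagged
#' degenerate (p = 0 when the mean is nonzero, p = 1 when it is zero).
#'
#' @param fc A `fold_change_table` from [center_on_controls()].
#' @return Data frame with columns `feature`, `n`, `mean_fc`, `t`, `df`,
#'   `p`, `flag`.
#' @export
lipid_ttest <- function(fc) {
  stopifnot(inherits(fc, "fold_change_table"))
  treated <- fc$centered[, fc$samples$arm == "treated", drop = FALSE]
  n <- ncol(treated)
  feats <- rownames(treated)
  if (n < 2L) {
    return(data.frame(feature = feats, n = n,
                      mean_fc = rowMeans(treated),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      flag = "insufficient_n", stringsAsFactors = FALSE))
  }
  mu <- rowMeans(treated)
  s <- apply(treated, 1L, stats::sd)
  tstat <- mu / (s / sqrt(n))
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tstat), df)
  flag <- rep("", length(mu))
  zero_var <- s == 0
  flag[zero_var & mu != 0] <- "degenerate_variance"
  flag[zero_var & mu == 0] <- "degenerate_variance"
  p[zero_var & mu != 0] <- 0
  p[zero_var & mu == 0] <- 1
  tstat[zero_var & mu == 0] <- 0
  data.frame(feature = feats, n = n, mean_fc = mu, t = tstat, df = df,
             p = p, flag = flag, stringsAsFactors = FALSE)
}

# Exact two-sided binomial p-value by the minimum-likelihood method: the sum
# of the probabilities of all outcomes no more likely than the observed one.
# At p0 = 0.5 the pmf is symmetric, so this coincides with doubling the
# smaller tail.
exact_binom_p <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  pmf <- stats::dbinom(0:n, n, p0)
  min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
}

#' Class-level binomial sign test of lipid fold-changes
#'
#' Groups lipids into classes and, within each class, scores each lipid's
#' mean treated log fold-change as a success (> 0) or failure (< 0); exact
#' ties at zero are excluded but counted. The observed success proportion
#' is tested against 0.5 with an exact two-sided binomial test, and the
#' reported effect statistic is the natural-log ratio of the observed
#' proportion to 0.5 (zero when up- and down-regulated lipids balance;
#' `-Inf`/`log(2)` at the extremes).
#'
#' @param fc A `fold_change_table`, or a named numeric vector of per-lipid
#'   mean fold-changes.
#' @param class_map Data frame with columns `feature_id` and `class`
#'   covering every retained feature (or a named character vector mapping
#'   feature to class).
#' @return Data frame of class `"class_binomial"` with one row per class:
#'   `class`, `n_up`, `n_down`, `n_tie`, `n`, `p_hat`, `statistic`
#'   (`log(p_hat / 0.5)`), `p_value`, `flag`.
#' @examples
#' fc <- c(a = 1, b = 2, c = -0.5, d = 0.3)
#' cm <- data.frame(feature_id = names(fc), class = "PC")
#' class_binomial_test(fc, cm)
#' @export
class_binomial_test <- function(fc, class_map) {
  mean_fc <- if (inherits(fc, "fold_change_table")) fc$mean_fc else fc
  stopifnot(is.numeric(mean_fc), !is.null(names(mean_fc)))
  if (is.data.frame(class_map)) {
    stopifnot(all(c("feature_id", "class") %in% names(class_map)))
    cm <- stats::setNames(as.character(class_map$class),
                          class_map$feature_id)
  } else {
    cm <- class_map
  }
  unmapped <- setdiff(names(mean_fc), names(cm))
  if (length(unmapped) > 0L) {
    stop("feature(s) missing from class map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "),
         if (length(unmapped) > 5L) ", ..." else "", call. = FALSE)
  }
  classes <- cm[names(mean_fc)]
  out <- lapply(sort(unique(classes)), function(cl) {
    v <- mean_fc[classes == cl]
    n_up <- sum(v > 0)
    n_down <- sum(v < 0)
    n_tie <- sum(v == 0)
    n <- n_up + n_down
    if (n == 0L) {
      return(data.frame(class = cl, n_up = n_up, n_down = n_down,
                        n_tie = n_tie, n = n, p_hat = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        flag = "insufficient_data",
                        stringsAsFactors = FALSE))
    }
    p_hat <- n_up / n
    data.frame(class = cl, n_up = n_up, n_down = n_down, n_tie = n_tie,
               n = n, p_hat = p_hat, statistic = log(p_hat / 0.5),
               p_value = exact_binom_p(n_up, n, 0.5), flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "log_base") <- "natural"
  class(out) <- c("class_binomial", "data.frame")
  out
}

#' Differential lipidomics pipeline with class-level sign tests
#'
#' Runs the full analysis on a raw feature x sample intensity matrix:
#' total-intensity normalization, offset log-transform, detection-presence
#' filtering, per-patient centering on control means, per-lipid one-sample
#' t-tests of treated fold-changes against zero, and the class-level exact
#' binomial sign test. Returns a classed object with `print`, `summary`,
#' `coef` and `plot` methods.
#'
#' @param x A raw `intensity_matrix`, a `sim_lipidomics` dataset from
#'   [simulate_lipidomics()], or a plain numeric matrix (then `metadata`
#'   is required).
#' @param metadata Sample metadata data frame (`sample_id`, `patient`,
#'   `arm`); ignored when `x` carries its own.
#' @param class_map Feature-to-class map (data frame `feature_id`, `class`
#'   or named character vector); ignored when `x` carries its own.
#' @param presence_fraction Detection fraction required by the presence
#'   filter; default `2/3`.
#' @param presence_scope `"per_patient"` (default) or `"pooled"`; see
#'   [presence_filter()].
#' @param offset_rule Log-offset rule; see [log_transform()].
#' @param normalization `"total"` (default) or `"none"` for matrices
#'   normalized upstream.
#' @return Object of class `"lipid_diff"` with elements `fold_changes`
#'   (a `fold_change_table`), `lipid_tests` (per-lipid data frame),
#'   `class_results` (per-class data frame), `provenance`, and `call`.
#' @examples
#' sim <- simulate_lipidomics(sim_config(n_classes = 3, lipids_per_class = 8,
#'                                       seed = 7))
#' fit <- lipid_diff(sim)
#' summary(fit)
#' @export
lipid_diff <- function(x, metadata = NULL, class_map = NULL,
                       presence_fraction = 2 / 3,
                       presence_scope = c("per_patient", "pooled"),
                       offset_rule = c("multiplicative", "subtractive"),
                       normalization = c("total", "none")) {
  presence_scope <- match.arg(presence_scope)
  offset_rule <- match.arg(offset_rule)
  normalization <- match.arg(normalization)
  cl <- match.call()
  if (inherits(x, "sim_lipidomics")) {
    metadata <- x$metadata
    class_map <- x$class_map
    x <- x$values
  }
  if (is.matrix(x)) {
    if (is.null(metadata)) {
      stop("metadata is required with a plain matrix", call. = FALSE)
    }
    x <- intensity_matrix(x, metadata)
  }
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(class_map)) {
    stop("class_map is required", call. = FALSE)
  }
  n0 <- nrow(x$values)
  m <- if (normalization == "total") normalize_total(x) else {
    x$state <- "normalized"
    x
  }
  m <- log_transform(m, offset_rule = offset_rule)
  m <- presence_filter(m, fraction = presence_fraction,
                       scope = presence_scope)
  fc <- center_on_controls(m)
  lipid_tests <- lipid_ttest(fc)
  class_results <- class_binomial_test(fc, class_map)
  prov <- c(m$provenance, list(
    n_features_input = n0,
    n_features_retained = nrow(m$values),
    normalization = normalization,
    class_statistic_log_base = "natural"
  ))
  structure(
    list(fold_changes = fc, lipid_tests = lipid_tests,
         class_results = class_results, provenance = prov, call = cl),
    class = "lipid_diff"
  )
}

#' @export
print.lipid_diff <- function(x, ...) {
  cat("Differential lipidomics fit (class-level binomial sign test)\n")
  cat(sprintf("  features: %d retained of %d; treated samples: %d\n",
              x$provenance$n_features_retained,
              x$provenance$n_features_input,
              x$fold_changes$n_treated))
  cat(sprintf("  classes tested: %d; log offset delta = %.3g\n",
              nrow(x$class_results), x$provenance$log_offset))
  sig <- sum(x$class_results$p_value < 0.05, na.rm = TRUE)
  cat(sprintf("  classes with binomial p < 0.05: %d\n", sig))
  invisible(x)
}

#' @describeIn lipid_diff Per-class summary table ordered by p-value, plus
#'   per-lipid test counts.
#' @param object,... A `lipid_diff` object; further arguments are ignored.
#' @export
summary.lipid_diff <- function(object, ...) {
  res <- object$class_results
  res <- res[order(res$p_value), , drop = FALSE]
  out <- list(class_results = res,
              n_lipids = nrow(object$lipid_tests),
              n_lipids_p05 = sum(object$lipid_tests$p < 0.05, na.rm = TRUE),
              provenance = object$provenance)
  class(out) <- "summary.lipid_diff"
  out
}

#' @export
print.summary.lipid_diff <- function(x, digits = 4, ...) {
  cat("Class-level binomial sign tests (statistic = ln(p_hat / 0.5)):\n\n")
  df <- x$class_results
  df$p_hat <- round(df$p_hat, digits)
  df$statistic <- round(df$statistic, digits)
  df$p_value <- signif(df$p_value, digits)
  print(df[, c("class", "n_up", "n_down", "n_tie", "p_hat", "statistic",
               "p_value")], row.names = FALSE)
  cat(sprintf("\nPer-lipid t-tests: %d lipids, %d with p < 0.05\n",
              x$n_lipids, x$n_lipids_p05))
  invisible(x)
}

#' @describeIn lipid_diff Named vector of class log-ratio statistics.
#' @export
coef.lipid_diff <- function(object, ...) {
  stats::setNames(object$class_results$statistic,
                  object$class_results$class)
}

#' @describeIn lipid_diff Barplot of the class log-ratio statistics;
#'   classes with exact binomial p < 0.05 are shaded.
#' @export
plot.lipid_diff <- function(x, ...) {
  res <- x$class_results
  ok <- is.finite(res$statistic)
  stat <- res$statistic[ok]
  sig <- res$p_value[ok] < 0.05
  graphics::barplot(stat, names.arg = res$class[ok],
                    col = ifelse(sig, "steelblue", "grey80"),
                    ylab = "ln(proportion up / 0.5)",
                    main = "Class-level lipid sign statistics",
                    las = 2, ...)
  graphics::abline(h = 0)
  invisible(x)
}
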