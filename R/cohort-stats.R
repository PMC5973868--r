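# Cohort-level statistics: rank-sum metabolite comparisons with Storey
# q-values, endpoint t-tests, caliper tumor-volume and growth-inhibition
# metrics, and IHC immunoreactivity scoring.

#' Wilcoxon rank-sum test (exact for small tie-free samples)
#'
#' Compares two groups with the Mann-Whitney/Wilcoxon rank-sum test. With
#' `n_a + n_b <= 20` and no ties the two-sided p-value comes from the exact
#' null distribution of the U statistic (smaller tail doubled, capped at
#' 1); otherwise a normal approximation with continuity and tie correction
#' is used. The method actually applied is reported.
#'
#' @param a,b Numeric vectors, each with at least one value.
#' @return List with `statistic` (U for group `a`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  x <- c(a, b)
  r <- rank(x)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(x))
  if (n <= 20L && !ties) {
    p <- if (u > na * nb / 2) {
      2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, na, nb)
    }
    return(list(statistic = u, p_value = min(1, p), method = "exact"))
  }
  if (ties && n <= 20L) {
    message("ties present; falling back to the normal approximation")
  }
  tie_tab <- table(x)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u, p_value = 1, method = "normal_approx"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx")
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the proportion of true nulls pi0 from the p-value histogram on
#' a lambda grid, extrapolating a cubic smoothing spline to the largest
#' lambda and clamping to (0, 1], then converts p-values to q-values by the
#' step-up pass `q_i = min over p_j >= p_i of pi0 * m * p_j / rank_j`.
#' Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjusted p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid Grid for pi0 estimation; default
#'   `seq(0.05, 0.90, 0.05)`.
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return List of class `"qvalue_result"` with `p` (as given), `q`
#'   (parallel q-values), `pi0`, and `significant` (`q < 0.05`, the
#'   conventional call threshold).
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.90, by = 0.05),
                           pi0 = NULL) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NAs", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    lambda_grid <- sort(unique(lambda_grid))
    if (any(lambda_grid <= 0 | lambda_grid >= 1)) {
      stop("lambda grid must lie in (0, 1)", call. = FALSE)
    }
    pi0_lambda <- vapply(lambda_grid,
                         function(l) mean(p > l) / (1 - l), numeric(1L))
    if (length(lambda_grid) >= 4L) {
      fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    } else {
      pi0 <- pi0_lambda[length(pi0_lambda)]
    }
    pi0 <- min(1, pi0)
    if (pi0 <= 0) {
      warning("estimated pi0 <= 0; clamped to 1/m", call. = FALSE)
      pi0 <- 1 / m
    }
  } else {
    if (!is.numeric(pi0) || pi0 <= 0 || pi0 > 1) {
      stop("pi0 must lie in (0, 1]", call. = FALSE)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
  structure(list(p = p, q = q, pi0 = pi0, significant = q < 0.05),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("Storey q-values: m = %d, pi0 = %.4f, %d significant at q < 0.05\n",
              length(x$p), x$pi0, sum(x$significant)))
  invisible(x)
}

#' Two-sample endpoint t-test
#'
#' Two-sided two-sample t-test of endpoint measurements (e.g. final tumor
#' weights), pooled-variance by default with a Welch option.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param welch Use the Welch (unequal-variance) form; default `FALSE`.
#' @return List with `t`, `df`, `p_value`, `method`.
#' @export
endpoint_ttest <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value,
       method = if (welch) "welch" else "pooled")
}

#' Caliper tumor volume
#'
#' Ellipsoid approximation from caliper width and length:
#' `TV = width^2 x length x 0.52` (mm^3).
#'
#' @param width,length Caliper measurements in mm; must be positive.
#' @return Tumor volume(s) in mm^3.
#' @examples
#' tumor_volume(1, 1) # 0.52
#' @export
tumor_volume <- function(width, length) {
  if (!is.numeric(width) || !is.numeric(length) ||
      any(width <= 0) || any(length <= 0)) {
    stop("width and length must be positive", call. = FALSE)
  }
  width^2 * length * 0.52
}

#' Baseline-normalized fold-change curves
#'
#' Divides each animal's volume series by its first (baseline) measurement,
#' so every curve starts at 1. The same contract applies to body-weight
#' series.
#'
#' @param growth Data frame with columns `animal_id`, `week`, and either
#'   `volume_mm3` or both `width_mm` and `length_mm` (converted with
#'   [tumor_volume()]); a `weight_g` column can be folded instead via
#'   `value_col`.
#' @param value_col Column to normalize; default `"volume_mm3"`.
#' @return The input with an added `fold_change` column.
#' @export
fold_change_curves <- function(growth, value_col = "volume_mm3") {
  stopifnot(is.data.frame(growth),
            all(c("animal_id", "week") %in% names(growth)))
  if (!value_col %in% names(growth)) {
    if (value_col == "volume_mm3" &&
        all(c("width_mm", "length_mm") %in% names(growth))) {
      growth$volume_mm3 <- tumor_volume(growth$width_mm, growth$length_mm)
    } else {
      stop("column '", value_col, "' not found", call. = FALSE)
    }
  }
  growth$fold_change <- NA_real_
  for (id in unique(growth$animal_id)) {
    ix <- which(growth$animal_id == id)
    ix <- ix[order(growth$week[ix])]
    base <- growth[[value_col]][ix[1L]]
    if (!is.finite(base) || base <= 0) {
      stop("animal '", id, "' has no positive baseline measurement",
           call. = FALSE)
    }
    growth$fold_change[ix] <- growth[[value_col]][ix] / base
  }
  growth
}

# Trapezoidal integral.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Span-normalized trapezoidal AUC of log fold-change for one animal,
# restricted (with linear interpolation at the ends) to [t0, t1].
aauc_one <- function(week, fold_change, t0, t1) {
  o <- order(week)
  week <- week[o]; y <- log(fold_change[o])
  grid <- sort(unique(c(t0, t1, week[week > t0 & week < t1])))
  yy <- stats::approx(week, y, xout = grid, rule = 2)$y
  trapz(grid, yy) / (t1 - t0)
}

#' AUC-based tumor growth inhibition with bootstrap confidence interval
#'
#' For each animal, computes the adjusted AUC (aAUC): the trapezoidal area
#' under its log baseline-fold-change curve over the span of weeks shared
#' by all animals, divided by the span length. Growth inhibition is
#' `TGI = 1 - mean(treated aAUC) / mean(control aAUC)`, with a percentile
#' bootstrap confidence interval over animals (resampled within arms, fixed
#' seed).
#'
#' @param growth A `growth_records` data frame (or any data frame with
#'   `animal_id`, `arm`, `week`, `volume_mm3`), both arms present with at
#'   least two animals each.
#' @param n_boot Bootstrap replicates; default 2000.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level; default 0.95.
#' @return Object of class `"tgi_result"`: list with `tgi`, `ci`
#'   (`lower`/`upper`), `level`, `aauc` (per-animal data frame),
#'   `aauc_control`, `aauc_treated`, `n_boot`, `flag` (nonempty when the
#'   control mean aAUC is not positive and TGI is undefined).
#' @examples
#' g <- simulate_growth(5, 5, 0.3, 0.05, noise_sd = 0.1, seed = 3)
#' auc_tgi(g, n_boot = 200, seed = 3)
#' @export
auc_tgi <- function(growth, n_boot = 2000L, seed = 1L, level = 0.95) {
  stopifnot(is.data.frame(growth),
            all(c("animal_id", "arm", "week", "volume_mm3") %in%
                  names(growth)))
  growth <- fold_change_curves(as.data.frame(growth))
  ids <- unique(growth$animal_id)
  arm_of <- vapply(ids, function(id) {
    growth$arm[match(id, growth$animal_id)]
  }, character(1L))
  if (sum(arm_of == "control") < 2L || sum(arm_of == "treated") < 2L) {
    stop("need at least two animals per arm", call. = FALSE)
  }
  spans <- vapply(ids, function(id) {
    w <- growth$week[growth$animal_id == id]
    c(min(w), max(w))
  }, numeric(2L))
  t0 <- max(spans[1L, ]); t1 <- min(spans[2L, ])
  if (t1 <= t0) stop("animals share no common time span", call. = FALSE)
  aauc <- vapply(ids, function(id) {
    g <- growth[growth$animal_id == id, ]
    aauc_one(g$week, g$fold_change, t0, t1)
  }, numeric(1L))
  per_animal <- data.frame(animal_id = ids, arm = unname(arm_of),
                           aauc = unname(aauc), stringsAsFactors = FALSE)
  mc <- mean(aauc[arm_of == "control"])
  mt <- mean(aauc[arm_of == "treated"])
  flag <- ""
  if (mc <= 0) {
    tgi <- NA_real_
    flag <- "control_mean_aauc_nonpositive"
    ci <- c(lower = NA_real_, upper = NA_real_)
  } else {
    tgi <- 1 - mt / mc
    ac <- aauc[arm_of == "control"]; at <- aauc[arm_of == "treated"]
    boot <- with_seed(substream_seed(seed, "tgi_bootstrap"), {
      vapply(seq_len(n_boot), function(i) {
        bc <- mean(sample(ac, replace = TRUE))
        bt <- mean(sample(at, replace = TRUE))
        if (bc <= 0) NA_real_ else 1 - bt / bc
      }, numeric(1L))
    })
    alpha <- (1 - level) / 2
    qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    ci <- c(lower = qs[1L], upper = qs[2L])
  }
  structure(
    list(tgi = tgi, ci = ci, level = level, aauc = per_animal,
         aauc_control = mc, aauc_treated = mt, n_boot = as.integer(n_boot),
         span = c(t0, t1), flag = flag),
    class = "tgi_result"
  )
}

#' @export
print.tgi_result <- function(x, digits = 4, ...) {
  cat("Tumor growth inhibition (adjusted AUC of log fold-change)\n")
  cat(sprintf("  aAUC control = %.4g, treated = %.4g (weeks %g-%g)\n",
              x$aauc_control, x$aauc_treated, x$span[1L], x$span[2L]))
  if (nzchar(x$flag)) {
    cat("  TGI undefined:", x$flag, "\n")
  } else {
    cat(sprintf("  TGI = %.4g  [%g%% CI %.4g, %.4g; %d bootstrap draws]\n",
                x$tgi, 100 * x$level, x$ci[["lower"]], x$ci[["upper"]],
                x$n_boot))
  }
  invisible(x)
}

#' Immunoreactivity score from IHC staining intensity and percent positive
#'
#' Multiplies the staining intensity code (0 none, 1 weak, 2 moderate,
#' 3 strong) by the percent-positive category (0: no positive cells;
#' 1: up to 10%; 2: 11-50%; 3: more than 50%). Fractional percentages
#' between 10 and 11 fall in category 1.
#'
#' @param intensity Integer code(s) in 0..3.
#' @param percent_positive Percent positive tumor cells in `[0, 100]`.
#' @return Integer score(s) in 0..9, with the derived `category` as an
#'   attribute.
#' @examples
#' irs_score(3, 80) # 9
#' @export
irs_score <- function(intensity, percent_positive) {
  if (!is.numeric(intensity) || any(!intensity %in% 0:3)) {
    stop("intensity must be an integer code in 0..3", call. = FALSE)
  }
  if (!is.numeric(percent_positive) ||
      any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must lie in [0, 100]", call. = FALSE)
  }
  category <- ifelse(percent_positive == 0, 0L,
                     ifelse(percent_positive < 11, 1L,
                            ifelse(percent_positive <= 50, 2L, 3L)))
  score <- as.integer(intensity) * category
  attr(score, "category") <- category
  score
}
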