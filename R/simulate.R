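# Seeded synthetic-data generators emulating the structure of a
# control-versus-treated PDX study: class-structured lipidomics matrices,
# tracer isotopologue vectors, and exponential tumor growth curves.
# Generator truth is always emitted alongside the data; downstream analysis
# code never reads it.

# Derive a per-stream substream seed from the global seed so adding a new
# generator does not shift the draws of existing ones.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.LIPID_CLASS_POOL <- c("PC", "PE", "PA", "PS", "PI", "SM", "Cer", "LacCer",
                       "HexCer", "TG", "DG", "FA", "LPC", "LPE", "CL")

#' Configuration for the synthetic lipidomics generator
#'
#' Captures the design of the emulated study: several patients (PDX
#' models), each with control and treated replicate samples; lipids grouped
#' into classes; a log-scale treatment effect per class; lognormal baseline
#' intensities with per-sample measurement noise; and
#' missing-completely-at-random undetected cells. Defaults mirror a
#' three-model design with five animals per arm.
#'
#' @param n_patients Number of patients (PDX models); default 3.
#' @param n_control,n_treated Replicate samples per patient and arm;
#'   default 5 each.
#' @param n_classes Number of lipid classes; default 10.
#' @param lipids_per_class Lipids per class; default 15.
#' @param class_effects Log-scale (natural log) treatment shift per class.
#'   A single value is recycled; a vector must have length `n_classes`;
#'   a named vector must name the generated classes. Default 0 (null).
#' @param lipid_noise_sd Per-sample log-scale measurement noise sd applied
#'   to every sample; default 0.25.
#' @param detection_rate Probability a cell is observed; cells are zeroed
#'   independently with probability `1 - detection_rate`. Default 1.
#' @param baseline_log_mean,baseline_log_sd Per-lipid baseline log
#'   intensity distribution; defaults `log(1e6)` and 1.5.
#' @param patient_effect_sd Sd of a per-(patient, lipid) baseline offset,
#'   shared by both arms of the patient (removed exactly by the pipeline's
#'   patient centering); default 0.5.
#' @param seed Integer seed; identical config + seed give bit-identical
#'   output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 3L, n_control = 5L, n_treated = 5L,
                       n_classes = 10L, lipids_per_class = 15L,
                       class_effects = 0, lipid_noise_sd = 0.25,
                       detection_rate = 1, baseline_log_mean = log(1e6),
                       baseline_log_sd = 1.5, patient_effect_sd = 0.5,
                       seed = 1L) {
  chk_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x)) {
      stop("'", name, "' must be a count >= 1", call. = FALSE)
    }
    as.integer(x)
  }
  cfg <- list(
    n_patients = chk_count(n_patients, "n_patients"),
    n_control = chk_count(n_control, "n_control"),
    n_treated = chk_count(n_treated, "n_treated"),
    n_classes = chk_count(n_classes, "n_classes"),
    lipids_per_class = chk_count(lipids_per_class, "lipids_per_class")
  )
  if (!is.numeric(lipid_noise_sd) || lipid_noise_sd < 0) {
    stop("'lipid_noise_sd' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(patient_effect_sd) || patient_effect_sd < 0) {
    stop("'patient_effect_sd' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(detection_rate) || length(detection_rate) != 1L ||
      detection_rate <= 0 || detection_rate > 1) {
    stop("'detection_rate' must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(baseline_log_sd) || baseline_log_sd < 0) {
    stop("'baseline_log_sd' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  classes <- if (cfg$n_classes <= length(.LIPID_CLASS_POOL)) {
    .LIPID_CLASS_POOL[seq_len(cfg$n_classes)]
  } else {
    c(.LIPID_CLASS_POOL,
      sprintf("Class%02d", seq_len(cfg$n_classes - length(.LIPID_CLASS_POOL))))
  }
  if (!is.numeric(class_effects)) {
    stop("'class_effects' must be numeric", call. = FALSE)
  }
  if (!is.null(names(class_effects)) && any(nzchar(names(class_effects)))) {
    bad <- setdiff(names(class_effects), classes)
    if (length(bad) > 0L) {
      stop("'class_effects' names unknown class(es): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    eff <- stats::setNames(rep(0, cfg$n_classes), classes)
    eff[names(class_effects)] <- class_effects
  } else if (length(class_effects) == 1L) {
    eff <- stats::setNames(rep(class_effects, cfg$n_classes), classes)
  } else if (length(class_effects) == cfg$n_classes) {
    eff <- stats::setNames(as.numeric(class_effects), classes)
  } else {
    stop("'class_effects' must have length 1 or n_classes, or be named",
         call. = FALSE)
  }
  cfg$class_effects <- eff
  cfg$lipid_noise_sd <- lipid_noise_sd
  cfg$detection_rate <- detection_rate
  cfg$baseline_log_mean <- baseline_log_mean
  cfg$baseline_log_sd <- baseline_log_sd
  cfg$patient_effect_sd <- patient_effect_sd
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic lipidomics dataset with known ground truth
#'
#' Draws a features x samples intensity matrix under the configured design:
#' log intensity = lipid baseline + patient x lipid offset + (class effect
#' if treated) + per-sample noise, exponentiated to a lognormal intensity;
#' cells are then zeroed independently with probability
#' `1 - detection_rate`. The true per-class and per-lipid treatment effects
#' are returned alongside the data.
#'
#' @param config A [sim_config()].
#' @return Object of class `"sim_lipidomics"`: list with `values`
#'   (intensity matrix), `metadata` (`sample_id`, `patient`, `arm`,
#'   `polarity`), `class_map` (`feature_id`, `class`), `truth` (per-class
#'   and per-lipid effects), and `config`.
#' @examples
#' sim <- simulate_lipidomics(sim_config(seed = 42))
#' dim(sim$values)
#' @export
simulate_lipidomics <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "lipidomics"), {
    classes <- names(config$class_effects)
    n_lip <- config$n_classes * config$lipids_per_class
    feature_class <- rep(classes, each = config$lipids_per_class)
    feature_id <- paste0(feature_class, "_",
                         formatC(rep(seq_len(config$lipids_per_class),
                                     times = config$n_classes),
                                 width = 2, flag = "0"))
    patients <- sprintf("PDX%d", seq_len(config$n_patients))
    meta <- do.call(rbind, lapply(patients, function(p) {
      data.frame(
        sample_id = c(sprintf("%s_C%d", p, seq_len(config$n_control)),
                      sprintf("%s_T%d", p, seq_len(config$n_treated))),
        patient = p,
        arm = c(rep("control", config$n_control),
                rep("treated", config$n_treated)),
        polarity = "negative",
        stringsAsFactors = FALSE
      )
    }))
    n_samp <- nrow(meta)
    baseline <- stats::rnorm(n_lip, config$baseline_log_mean,
                             config$baseline_log_sd)
    lipid_effect <- config$class_effects[feature_class]
    pat_offset <- matrix(stats::rnorm(n_lip * config$n_patients, 0,
                                      config$patient_effect_sd),
                         nrow = n_lip,
                         dimnames = list(NULL, patients))
    logx <- matrix(0, n_lip, n_samp,
                   dimnames = list(feature_id, meta$sample_id))
    for (s in seq_len(n_samp)) {
      logx[, s] <- baseline + pat_offset[, meta$patient[s]] +
        if (meta$arm[s] == "treated") lipid_effect else 0
    }
    logx <- logx + matrix(stats::rnorm(n_lip * n_samp, 0,
                                       config$lipid_noise_sd),
                          n_lip, n_samp)
    values <- exp(logx)
    if (config$detection_rate < 1) {
      drop <- matrix(stats::runif(n_lip * n_samp) > config$detection_rate,
                     n_lip, n_samp)
      values[drop] <- 0
    }
    structure(
      list(values = values,
           metadata = meta,
           class_map = data.frame(feature_id = feature_id,
                                  class = feature_class,
                                  stringsAsFactors = FALSE),
           truth = list(
             class_effects = config$class_effects,
             lipid_effects = stats::setNames(as.numeric(lipid_effect),
                                             feature_id)
           ),
           config = config),
      class = "sim_lipidomics"
    )
  })
}

#' @export
print.sim_lipidomics <- function(x, ...) {
  cat(sprintf(paste0("Synthetic lipidomics dataset: %d lipids ",
                     "(%d classes) x %d samples, %d patients\n"),
              nrow(x$values), x$config$n_classes, ncol(x$values),
              x$config$n_patients))
  invisible(x)
}

#' Generate a synthetic observed isotopologue vector
#'
#' Forward-convolves a true tracer enrichment distribution with natural 13C
#' abundance (see [na_convolve()]), scales it to instrument intensity, and
#' applies multiplicative lognormal noise. With zero noise,
#' [na_correction()] of the output recovers the input enrichment exactly.
#'
#' @param n_carbons Carbon count of the metabolite.
#' @param enrichment Probability vector over M+0 ... M+n (sums to 1).
#' @param intensity_scale Total signal scale; default 1e6.
#' @param noise_sd Sd of multiplicative log-scale noise; default 0.
#' @param p13C Natural 13C abundance; default 0.0107.
#' @param seed Integer seed.
#' @param metabolite Name for the returned vector.
#' @return An `isotopologue_vector` of observed (uncorrected) intensities.
#' @export
simulate_isotopologues <- function(n_carbons, enrichment,
                                   intensity_scale = 1e6, noise_sd = 0,
                                   p13C = 0.0107, seed = 1L,
                                   metabolite = "metabolite") {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 0L) stop("n_carbons must be >= 0", call. = FALSE)
  stopifnot(is.numeric(enrichment))
  if (length(enrichment) != n_carbons + 1L) {
    stop("enrichment must have length n_carbons + 1", call. = FALSE)
  }
  if (any(enrichment < 0) || abs(sum(enrichment) - 1) > 1e-8) {
    stop("enrichment must be a probability vector summing to 1",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(substream_seed(seed, "isotopologue"), {
    obs <- na_convolve(enrichment * intensity_scale, p13C)
    if (noise_sd > 0) {
      obs <- obs * exp(stats::rnorm(length(obs), 0, noise_sd))
    }
    isotopologue_vector(metabolite, obs, n_carbons, corrected = FALSE)
  })
}

#' Generate synthetic tumor growth curves
#'
#' Emulates weekly caliper follow-up of xenografts: each animal starts at
#' `baseline_mm3` and grows exponentially at its arm's rate, with
#' multiplicative lognormal measurement noise at every visit.
#'
#' @param n_per_arm Animals per arm (>= 2).
#' @param t_max_weeks Last follow-up week (>= 1); measurements at weeks
#'   0, 1, ..., `t_max_weeks`.
#' @param growth_rate_control,growth_rate_treated Exponential growth rates
#'   per week (natural-log scale).
#' @param noise_sd Sd of log-scale measurement noise; default 0.
#' @param seed Integer seed.
#' @param baseline_mm3 Starting tumor volume; default 100.
#' @return Data frame of class `"growth_records"` with columns `animal_id`,
#'   `arm`, `week`, `volume_mm3`, plus a `truth` attribute recording the
#'   configured rates.
#' @export
simulate_growth <- function(n_per_arm, t_max_weeks, growth_rate_control,
                            growth_rate_treated, noise_sd = 0, seed = 1L,
                            baseline_mm3 = 100) {
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop("n_per_arm must be >= 2", call. = FALSE)
  }
  if (!is.numeric(t_max_weeks) || t_max_weeks < 1) {
    stop("t_max_weeks must be >= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(substream_seed(seed, "growth"), {
    weeks <- 0:t_max_weeks
    arms <- c(control = growth_rate_control, treated = growth_rate_treated)
    out <- do.call(rbind, lapply(names(arms), function(a) {
      do.call(rbind, lapply(seq_len(n_per_arm), function(i) {
        vol <- baseline_mm3 * exp(arms[[a]] * weeks)
        if (noise_sd > 0) {
          vol <- vol * exp(stats::rnorm(length(weeks), 0, noise_sd))
        }
        data.frame(animal_id = sprintf("%s_%02d", a, i), arm = a,
                   week = weeks, volume_mm3 = vol,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- list(growth_rate_control = growth_rate_control,
                               growth_rate_treated = growth_rate_treated,
                               noise_sd = noise_sd)
    class(out) <- c("growth_records", "data.frame")
    out
  })
}
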