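# Stable-isotope-resolved metabolomics: natural-abundance 13C correction
# and enrichment summaries.

#' Construct an isotopologue intensity vector
#'
#' Container for the M+0 ... M+n intensities of one metabolite, where n is
#' its carbon count.
#'
#' @param metabolite Metabolite name.
#' @param intensities Nonnegative numeric vector of length `n_carbons + 1`,
#'   ordered M+0, M+1, ..., M+n.
#' @param n_carbons Number of carbon atoms; defaults to
#'   `length(intensities) - 1`.
#' @param corrected Logical; `TRUE` once natural abundance has been removed.
#' @return Object of class `"isotopologue_vector"`.
#' @export
isotopologue_vector <- function(metabolite, intensities,
                                n_carbons = length(intensities) - 1L,
                                corrected = FALSE) {
  stopifnot(is.numeric(intensities), length(intensities) >= 1L)
  n_carbons <- as.integer(n_carbons)
  if (length(intensities) != n_carbons + 1L) {
    stop("intensities must have length n_carbons + 1 (M+0 ... M+n); got ",
         length(intensities), " values for n_carbons = ", n_carbons,
         call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("isotopologue intensities must be nonnegative", call. = FALSE)
  }
  structure(
    list(metabolite = as.character(metabolite),
         n_carbons = n_carbons,
         intensities = as.numeric(intensities),
         corrected = isTRUE(corrected)),
    class = "isotopologue_vector"
  )
}

#' @export
print.isotopologue_vector <- function(x, ...) {
  cat("Isotopologue vector:", x$metabolite,
      sprintf("(n = %d carbons, %s)\n", x$n_carbons,
              if (x$corrected) "NA-corrected" else "observed"))
  v <- x$intensities
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(v, ...)
  invisible(x)
}

# Lower-triangular natural-abundance mixing matrix for n carbons at 13C
# probability p: entry [i+1, j+1] = P(i total heavy carbons | j tracer-labeled
# carbons) = dbinom(i - j, n - j, p), the remaining n - j carbons being
# subject to natural labeling.
na_matrix <- function(n_carbons, p13C) {
  n <- as.integer(n_carbons)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    M[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), n - j, p13C)
  }
  M
}

#' Forward-convolve a tracer enrichment pattern with natural 13C abundance
#'
#' Maps a "true" isotopologue distribution (tracer labeling only) to the
#' pattern an instrument observes when every non-tracer carbon carries 13C
#' independently with probability `p13C`. This is the exact inverse of
#' [na_correction()].
#'
#' @param x Numeric vector (M+0 ... M+n) or an `isotopologue_vector`.
#' @param p13C Natural 13C abundance, in `[0, 0.05]`; default 0.0107.
#' @return Same type as `x`, convolved.
#' @export
na_convolve <- function(x, p13C = 0.0107) {
  .check_p13C(p13C)
  if (inherits(x, "isotopologue_vector")) {
    out <- x
    out$intensities <- as.numeric(na_matrix(x$n_carbons, p13C) %*%
                                    x$intensities)
    out$corrected <- FALSE
    return(out)
  }
  stopifnot(is.numeric(x))
  as.numeric(na_matrix(length(x) - 1L, p13C) %*% x)
}

.check_p13C <- function(p13C) {
  if (!is.numeric(p13C) || length(p13C) != 1L || p13C < 0 || p13C > 0.05) {
    stop("p13C must be a single probability in [0, 0.05]", call. = FALSE)
  }
  invisible(p13C)
}

#' Correct an observed isotopologue vector for natural 13C abundance
#'
#' Solves the lower-triangular binomial mixing system M x = observed by
#' forward substitution, where `M[i, j]` is the probability that a molecule
#' with `j` tracer-labeled carbons shows `i` total heavy carbons through
#' natural labeling of its remaining carbons. Negative corrected components
#' (noise artifacts) are clipped to zero with a warning and the vector is
#' rescaled to preserve the total signal of the exact solution.
#'
#' @param observed An `isotopologue_vector` (or plain numeric vector
#'   M+0 ... M+n) of observed intensities.
#' @param p13C Natural 13C abundance in `[0, 0.05]`; default 0.0107, the
#'   standard terrestrial value.
#' @return Corrected object of the same type, with `corrected = TRUE` when
#'   the input is an `isotopologue_vector`. A `"clipped"` attribute on the
#'   numeric result records how many components were clipped.
#' @examples
#' obs <- na_convolve(c(100, 0, 0, 50), p13C = 0.011)
#' na_correction(isotopologue_vector("succinate", obs), p13C = 0.011)
#' @export
na_correction <- function(observed, p13C = 0.0107) {
  .check_p13C(p13C)
  if (inherits(observed, "isotopologue_vector")) {
    out <- observed
    out$intensities <- na_correction(observed$intensities, p13C)
    attr(out$intensities, "clipped") <- NULL
    out$corrected <- TRUE
    return(out)
  }
  stopifnot(is.numeric(observed), length(observed) >= 1L)
  n <- length(observed) - 1L
  if (p13C == 0) {
    out <- as.numeric(observed)
    attr(out, "clipped") <- 0L
    return(out)
  }
  M <- na_matrix(n, p13C)
  x <- as.numeric(forwardsolve(M, observed))
  # negatives at floating-point scale are rounding, not signal; zero them
  # silently and only warn (and renormalize) for material negatives
  tol <- 1e-12 * max(sum(abs(x)), 1)
  material <- x < -tol
  nclip <- sum(material)
  if (nclip > 0L) {
    total <- sum(x)
    warning(nclip, " corrected isotopologue component(s) were negative; ",
            "clipped to zero and renormalized", call. = FALSE)
    x <- pmax(x, 0)
    s <- sum(x)
    if (s > 0 && total > 0) x <- x * (total / s)
  } else {
    x <- pmax(x, 0)
  }
  attr(x, "clipped") <- nclip
  x
}

#' Fractional and absolute enrichment of an isotopologue vector
#'
#' Fractional enrichment of isotopologue M+i is its share of the total
#' intensity; absolute enrichments are the intensities themselves (in
#' whatever amount unit the input carries, e.g. nmol per mg protein).
#'
#' @param v An `isotopologue_vector` or numeric vector with positive total.
#' @return List of class `"enrichment_profile"` with elements `fractional`
#'   (sums to 1) and `absolute`.
#' @export
fractional_enrichment <- function(v) {
  x <- if (inherits(v, "isotopologue_vector")) v$intensities else v
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("intensities must be nonnegative", call. = FALSE)
  total <- sum(x)
  if (total <= 0) {
    stop("fractional enrichment undefined for an all-zero vector",
         call. = FALSE)
  }
  out <- list(fractional = x / total, absolute = as.numeric(x))
  names(out$fractional) <- names(out$absolute) <-
    paste0("M+", seq_along(x) - 1L)
  class(out) <- "enrichment_profile"
  out
}

#' @export
print.enrichment_profile <- function(x, digits = 4, ...) {
  cat("Enrichment profile (total =", format(sum(x$absolute), digits = digits),
      ")\n")
  print(round(rbind(fractional = x$fractional, absolute = x$absolute),
              digits), ...)
  invisible(x)
}

#' Normalize a quantity to protein content
#'
#' @param quantity Measured amount(s).
#' @param mg_protein Protein content in mg (BCA or equivalent); must be
#'   positive.
#' @return `quantity / mg_protein`.
#' @export
normalize_to_protein <- function(quantity, mg_protein) {
  if (!is.numeric(mg_protein) || any(mg_protein <= 0)) {
    stop("mg_protein must be positive", call. = FALSE)
  }
  quantity / mg_protein
}

#' Sum a metabolite pool (e.g. AXP = ATP + ADP + AMP)
#'
#' Sums the pool members present in `quantities`; absent members are
#' tolerated and reported through a completeness attribute, since real
#' panels routinely miss individual species.
#'
#' @param quantities Named numeric vector or list of metabolite amounts.
#' @param members Character vector of pool member names (nonempty).
#' @param pool Optional pool label used in messages.
#' @return The pool sum, with attributes `completeness` (fraction of
#'   members present) and `missing` (absent member names).
#' @examples
#' pool_sum(c(ATP = 3, ADP = 2, AMP = 1), c("ATP", "ADP", "AMP"), "AXP")
#' @export
pool_sum <- function(quantities, members, pool = "pool") {
  quantities <- unlist(quantities)
  stopifnot(is.numeric(quantities), !is.null(names(quantities)))
  if (length(members) == 0L) stop("pool has no members", call. = FALSE)
  present <- intersect(members, names(quantities))
  if (length(present) == 0L) {
    stop("no member of ", pool, " present in quantities", call. = FALSE)
  }
  out <- sum(quantities[present])
  attr(out, "completeness") <- length(present) / length(members)
  attr(out, "missing") <- setdiff(members, present)
  out
}

#' Ratio of labeled metabolite signals and its treatment percent change
#'
#' `labeled_ratio()` forms e.g. the 13C-lactate / 13C-glucose ratio;
#' `percent_change()` expresses a treated-versus-control shift of such a
#' ratio in percent (negative = decrease under treatment).
#'
#' @param numerator_13C,denominator_13C Labeled signal amounts; the
#'   denominator must be positive.
#' @return `labeled_ratio()`: the ratio.
#' @export
labeled_ratio <- function(numerator_13C, denominator_13C) {
  if (!is.numeric(denominator_13C) || any(denominator_13C <= 0)) {
    stop("denominator must be positive", call. = FALSE)
  }
  numerator_13C / denominator_13C
}

#' @rdname labeled_ratio
#' @param control_ratio,treated_ratio Ratios in the two arms; the control
#'   ratio must be positive.
#' @return `percent_change()`: `100 * (treated - control) / control`.
#' @export
percent_change <- function(control_ratio, treated_ratio) {
  if (!is.numeric(control_ratio) || any(control_ratio <= 0)) {
    stop("control ratio must be positive", call. = FALSE)
  }
  100 * (treated_ratio - control_ratio) / control_ratio
}
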