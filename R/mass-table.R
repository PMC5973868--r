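# Exact-mass bookkeeping for direct-infusion FT-MS lipid assignment.
# All masses in Da (unified atomic mass units), monoisotopic.

# Monoisotopic atomic masses (CODATA/AME-derived values, truncated well below
# the 0.5 ppm instrument accuracy that matters here).
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885271,
  F  = 18.99840322
)

# 13C minus 12C: spacing of successive carbon isotopologues in neutral mass.
.DELTA_13C <- 13.0033548378 - 12.0

.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula in Hill notation
#'
#' Converts a formula string such as `"C16H32O2"` into a named integer
#' vector of element counts. Only elements with a known monoisotopic mass
#' are accepted (C, H, N, O, P, S, Na, K, Cl, F).
#'
#' @param formula A single formula string, e.g. `"C43H81NO3"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C16H32O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(.MONOISOTOPIC))
  if (length(unknown) > 0L) {
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sums <- tapply(counts, elements, sum)
  stats::setNames(as.integer(sums), names(sums))
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums count times monoisotopic atomic mass over the formula's elements.
#' The empty formula has mass zero.
#'
#' @param formula Either a formula string (see [parse_formula()]) or a
#'   named numeric vector of element counts.
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' monoisotopic_mass("C16H32O2") # palmitic acid, ~256.2402 Da
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0.0)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  if (any(formula < 0)) stop("element counts must be >= 0", call. = FALSE)
  unknown <- setdiff(names(formula), names(.MONOISOTOPIC))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(formula * .MONOISOTOPIC[names(formula)])
}

#' Default electrospray adduct set
#'
#' Adducts typical of ammonium-formate-modified direct infusion: protonated,
#' sodiated and ammoniated species in positive mode; deprotonated and
#' formate adducts in negative mode. Mass shifts include the electron mass
#' so that m/z values refer to the actual charged species.
#'
#' @param polarity `"positive"`, `"negative"`, or `"both"` (default).
#' @return A data frame with columns `adduct`, `delta_mass`, `charge`.
#' @export
default_adducts <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  h <- .MONOISOTOPIC[["H"]]; e <- .ELECTRON_MASS
  formate <- monoisotopic_mass(c(C = 1, H = 1, O = 2))
  nh4 <- monoisotopic_mass(c(N = 1, H = 4))
  tab <- data.frame(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+HCOO]-"),
    delta_mass = c(h - e, .MONOISOTOPIC[["Na"]] - e, nh4 - e,
                   -h + e, formate + e),
    charge = c(1L, 1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
  switch(polarity,
         both = tab,
         positive = tab[tab$charge > 0, , drop = FALSE],
         negative = tab[tab$charge < 0, , drop = FALSE])
}

#' Build a precalculated exact-mass isotopologue table
#'
#' For every species x adduct combination, tabulates the exact m/z of the
#' carbon isotopologues M+0 ... M+k (k capped at the species' carbon count),
#' with m/z(k) = (monoisotopic mass + adduct shift + k * d13C) / |charge|.
#' Observed peaks are later matched against this table at ppm tolerance.
#'
#' @param species Data frame with columns `name`, `class`, `formula`
#'   (Hill-notation string). A `n_carbons` column is derived from the
#'   formula if absent, and validated against it if present.
#' @param adducts Data frame as returned by [default_adducts()].
#' @param max_k Maximum isotopologue index to tabulate (clamped per species
#'   to its carbon count).
#' @return A data frame of class `"mass_table"` with columns `species`,
#'   `class`, `adduct`, `k`, `mz`, `charge`, sorted by `mz`.
#' @export
build_mass_table <- function(species, adducts = default_adducts(),
                             max_k = 3L) {
  stopifnot(is.data.frame(species),
            all(c("name", "formula") %in% names(species)),
            is.data.frame(adducts),
            all(c("adduct", "delta_mass", "charge") %in% names(adducts)),
            max_k >= 0L)
  if (nrow(species) == 0L) {
    out <- data.frame(species = character(), class = character(),
                      adduct = character(), k = integer(),
                      mz = numeric(), charge = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mass_table", "data.frame")
    return(out)
  }
  if (anyDuplicated(species$name)) {
    stop("duplicated species names in database", call. = FALSE)
  }
  if (is.null(species$class)) species$class <- NA_character_
  formulas <- lapply(species$formula, parse_formula)
  ncarb <- vapply(formulas, function(f) {
    as.integer(if ("C" %in% names(f)) f[["C"]] else 0L)
  }, integer(1L))
  if (!is.null(species$n_carbons)) {
    bad <- which(as.integer(species$n_carbons) != ncarb)
    if (length(bad) > 0L) {
      stop("n_carbons disagrees with formula for: ",
           paste(species$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  mono <- vapply(formulas, monoisotopic_mass, numeric(1L))
  rows <- vector("list", nrow(species) * nrow(adducts))
  idx <- 0L
  for (i in seq_len(nrow(species))) {
    ks <- 0:min(max_k, ncarb[i])
    for (j in seq_len(nrow(adducts))) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        species = species$name[i],
        class = species$class[i],
        adduct = adducts$adduct[j],
        k = ks,
        mz = (mono[i] + adducts$delta_mass[j] + ks * .DELTA_13C) /
          abs(adducts$charge[j]),
        charge = adducts$charge[j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mz, out$species, out$adduct, out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mass_table", "data.frame")
  out
}

#' Assign observed m/z peaks to mass-table entries at ppm tolerance
#'
#' Each peak is matched to the table entry that minimizes the absolute ppm
#' error, provided that error is within `tol_ppm`; peaks with no entry in
#' the window are reported as unassigned. Ties on |ppm| (within 1e-9 ppm)
#' are broken toward the lower calculated m/z, then the lexicographically
#' first species name, and flagged ambiguous. Several peaks may share one
#' table entry.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param table A `mass_table` from [build_mass_table()].
#' @param tol_ppm Match window in parts per million (default 1.0, i.e.
#'   twice a 0.5 ppm instrument accuracy).
#' @param polarity Optional `"positive"`/`"negative"`; restricts the table
#'   to entries of matching charge sign.
#' @return List with `assignments` (data frame: `peak`, `mz_obs`,
#'   `intensity`, `species`, `class`, `adduct`, `k`, `mz_calc`, `ppm`,
#'   `ambiguous`) and `unassigned` (integer peak indices).
#' @export
assign_peaks <- function(peaks, table, tol_ppm = 1.0, polarity = NULL) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)),
            tol_ppm > 0)
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (any(peaks$intensity < 0)) {
    stop("peak intensities must be nonnegative", call. = FALSE)
  }
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("positive", "negative"))
    keep <- if (polarity == "positive") table$charge > 0 else table$charge < 0
    table <- table[keep, , drop = FALSE]
  }
  empty <- data.frame(peak = integer(), mz_obs = numeric(),
                      intensity = numeric(), species = character(),
                      class = character(), adduct = character(),
                      k = integer(), mz_calc = numeric(), ppm = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(table) == 0L) {
    return(list(assignments = empty, unassigned = seq_len(nrow(peaks))))
  }
  table <- table[order(table$mz), , drop = FALSE]
  tmz <- table$mz
  hits <- vector("list", nrow(peaks))
  unassigned <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    mz <- peaks$mz[i]
    win <- mz * tol_ppm * 1e-6
    lo <- findInterval(mz - win, tmz) + 1L
    hi <- findInterval(mz + win, tmz)
    if (hi < lo) { unassigned <- c(unassigned, i); next }
    cand <- lo:hi
    ppm <- 1e6 * (mz - tmz[cand]) / tmz[cand]
    ok <- abs(ppm) <= tol_ppm
    cand <- cand[ok]; ppm <- ppm[ok]
    if (length(cand) == 0L) { unassigned <- c(unassigned, i); next }
    best <- min(abs(ppm))
    tied <- which(abs(abs(ppm) - best) <= 1e-9)
    if (length(tied) > 1L) {
      ord <- order(tmz[cand[tied]], table$species[cand[tied]])
      pick <- tied[ord[1L]]
      ambiguous <- TRUE
    } else {
      pick <- tied
      ambiguous <- FALSE
    }
    j <- cand[pick]
    hits[[i]] <- data.frame(
      peak = i, mz_obs = mz, intensity = peaks$intensity[i],
      species = table$species[j], class = table$class[j],
      adduct = table$adduct[j], k = table$k[j], mz_calc = tmz[j],
      ppm = ppm[pick], ambiguous = ambiguous, stringsAsFactors = FALSE
    )
  }
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  assignments <- if (length(hits) > 0L) do.call(rbind, hits) else empty
  rownames(assignments) <- NULL
  list(assignments = assignments, unassigned = unassigned)
}

#' Read a two-column peak list (m/z, intensity) from delimited text
#'
#' @param path Path to a tab- or comma-delimited file with a header and
#'   columns `mz` and `intensity`.
#' @param sep Field separator; `"\t"` by default.
#' @return Data frame sorted ascending by `mz`.
#' @export
read_peaklist <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list must have 'mz' and 'intensity' columns", call. = FALSE)
  }
  df <- df[order(df$mz), c("mz", "intensity"), drop = FALSE]
  rownames(df) <- NULL
  df
}
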