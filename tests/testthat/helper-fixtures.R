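# Shared fixtures and independent oracles used across test files.

# Small intensity matrix with explicit metadata; values by column.
toy_matrix <- function(values, n_control, n_treated, patients = NULL,
                       n_features = NULL) {
  n_samp <- n_control + n_treated
  if (is.null(n_features)) n_features <- length(values) / n_samp
  m <- matrix(values, nrow = n_features, ncol = n_samp)
  rownames(m) <- paste0("lip", seq_len(n_features))
  colnames(m) <- paste0("s", seq_len(n_samp))
  if (is.null(patients)) patients <- rep("P1", n_samp)
  meta <- data.frame(
    sample_id = colnames(m),
    patient = patients,
    arm = c(rep("control", n_control), rep("treated", n_treated)),
    stringsAsFactors = FALSE
  )
  intensity_matrix(m, meta)
}

# Independent oracle: exact two-sided binomial p at p0 = 0.5 by direct
# enumeration of the pmf via choose()/2^n (no dbinom).
enum_binom_p <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-9)]))
}

# Independent oracle: exact two-sided rank-sum p by enumerating every
# assignment of ranks to group a (combn), doubling the smaller tail of the
# enumerated U distribution.
enum_wilcox_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(ix) sum(seq_len(n)[ix]) -
                   na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}
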