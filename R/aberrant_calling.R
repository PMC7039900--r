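#' One-sample two-sided t test of a patient PSI against controls
#'
#' Tests whether the control PSI population mean equals the patient's
#' observed PSI: `t = (mean(controls) - patient) / (sd(controls)/sqrt(n))`
#' with a two-sided p value on `n - 1` degrees of freedom. The control
#' vector is zero-assigned (PSI 0 for controls without the event). When
#' the controls have zero variance the test is degenerate: p is 1 if the
#' patient equals the common control value and 0 (flagged) otherwise —
#' the latter is how an event absent from every control but present in
#' the patient is scored.
#'
#' @param control_psis Numeric vector of control PSIs (length >= 2).
#' @param patient_psi Scalar patient PSI.
#' @return List `t`, `p`, `df`, `degenerate`.
#' @export
one_sample_t <- function(control_psis, patient_psi) {
  n <- length(control_psis)
  if (n < 2L) stop("need at least 2 control values")
  stopifnot(length(patient_psi) == 1L, is.finite(patient_psi))
  m <- mean(control_psis)
  s <- stats::sd(control_psis)
  if (s == 0) {
    if (m == patient_psi) {
      return(list(t = 0, p = 1, df = n - 1L, degenerate = FALSE))
    }
    return(list(t = sign(m - patient_psi) * Inf, p = 0, df = n - 1L,
                degenerate = TRUE))
  }
  t <- (m - patient_psi) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       degenerate = FALSE)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Orders the m raw p values ascending, applies the Sidak formula
#' `1 - (1 - p_(i))^(m - i + 1)` to the i-th smallest, enforces
#' monotonicity with a running maximum, caps at 1, and restores the input
#' order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of adjusted p values, same order as input.
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  k <- m - seq_len(m) + 1L
  # -expm1(k*log1p(-p)) = 1 - (1-p)^k, stable for small p
  adj <- -expm1(k * log1p(-p[o]))
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Call aberrant splicing events in one patient sample
#'
#' Every event detected in the patient (PSI > 0) is tested against the
#' control profile's zero-assigned PSI vector with [one_sample_t()];
#' events absent from the profile are tested against an all-zero vector
#' (degenerate branch) and flagged `novel_in_patient`. Events whose
#' patient PSI is not above the control mean are excluded from the tested
#' family before Holm-Sidak adjustment, as are events failing the PSI and
#' coverage gates. A call is significant when all four criteria hold:
#' patient PSI >= `psi_min`, patient PSI above the control mean, adjusted
#' p below `alpha`, and region reads >= `min_region_reads`.
#'
#' @param patient_quants Quantification rows of one patient sample
#'   ([quantify_sample()]).
#' @param profile A [build_profile()] control profile.
#' @param alpha Significance level for the adjusted p (default 0.05).
#' @param psi_min Minimum patient PSI (percent, default 5).
#' @param min_region_reads Minimum region coverage (reads, default 50).
#' @return Data frame, one row per detected patient event: patient and
#'   control summaries, `t_statistic`, `p_raw`, `p_adjusted` (NA outside
#'   the tested family), `degenerate`, `tested`, `significant`,
#'   `novel_in_patient`.
#' @export
call_aberrant <- function(patient_quants, profile, alpha = 0.05,
                          psi_min = 5, min_region_reads = 50) {
  stopifnot(inherits(profile, "control_profile"))
  if (!nrow(profile$stats)) stop("control profile is empty")
  q <- patient_quants[!is.na(patient_quants$psi) & patient_quants$psi > 0, ,
                      drop = FALSE]
  if (!nrow(q)) {
    return(data.frame(sample_id = character(), gene = character(),
                      event = character(), patient_psi = numeric(),
                      patient_region_reads = integer(),
                      control_mean_psi = numeric(), control_sd_psi = numeric(),
                      control_median_psi = numeric(), control_iqr_lo = numeric(),
                      control_iqr_hi = numeric(), n_controls = integer(),
                      n_controls_detected = integer(), t_statistic = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      degenerate = logical(), tested = logical(),
                      significant = logical(), novel_in_patient = logical()))
  }
  n <- profile$n_controls
  zeros <- rep(0, n)
  key <- paste0(q$gene, ":", q$event)
  rows <- lapply(seq_len(nrow(q)), function(i) {
    in_prof <- key[i] %in% rownames(profile$psi)
    cv <- if (in_prof) profile$psi[key[i], ] else zeros
    st <- profile$stats[match(key[i], profile$stats$key), ]
    tt <- one_sample_t(cv, q$psi[i])
    data.frame(
      sample_id = q$sample_id[i], gene = q$gene[i], event = q$event[i],
      patient_psi = q$psi[i], patient_region_reads = q$region_reads[i],
      control_mean_psi = mean(cv), control_sd_psi = stats::sd(cv),
      control_median_psi = if (in_prof) st$median_psi else NA_real_,
      control_iqr_lo = if (in_prof) st$iqr_lo else NA_real_,
      control_iqr_hi = if (in_prof) st$iqr_hi else NA_real_,
      n_controls = n,
      n_controls_detected = if (in_prof) st$n_detected else 0L,
      t_statistic = tt$t, p_raw = tt$p, p_adjusted = NA_real_,
      degenerate = tt$degenerate, tested = FALSE, significant = FALSE,
      novel_in_patient = !in_prof
    )
  })
  calls <- do.call(rbind, rows)
  direction <- calls$patient_psi > calls$control_mean_psi
  gates <- calls$patient_psi >= psi_min &
    calls$patient_region_reads >= min_region_reads
  family <- direction & gates
  calls$tested <- family
  if (any(family)) {
    calls$p_adjusted[family] <- holm_sidak(calls$p_raw[family])
    calls$significant <- family & !is.na(calls$p_adjusted) &
      calls$p_adjusted < alpha
  }
  rownames(calls) <- NULL
  calls
}
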