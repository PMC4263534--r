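## Residue-level averaging and time statistics of stress series:
## mean, mean square fluctuation (MSF, population-normalized), and the
## standard error of the mean corrected by the statistical inefficiency g
## of the time series (effective sample size N/g).

.TERM_COLS <- c("bond", "angle", "dihedral", "coulomb", "vdw", "gb",
                "kinetic", "total", "hydrostatic_pressure")

#' Residue-averaged stress series
#'
#' For every frame and residue, the arithmetic mean of the per-atom stress
#' over the residue's atoms (per term and total). Note such averages cannot
#' be re-summed into the system virial without shifting to per-residue
#' local frames; they are a visualization/statistics device.
#'
#' @param records an `atom_stress` data.frame from [atom_stress()]
#' @param top the matching `fftop` (residue map source); optional when
#'   `records` already carries a `resid` column
#' @return data.frame of class `residue_stress`: rows are (frame, residue)
#' @export
residue_average <- function(records, top = NULL) {
  if (!is.null(top)) {
    records$resid <- top$atoms$resid[records$atom]
  }
  if (is.null(records$resid) || any(is.na(records$resid)))
    stop("atom(s) without residue assignment", call. = FALSE)
  cols <- intersect(.TERM_COLS, names(records))
  agg <- stats::aggregate(records[cols],
                          by = list(frame = records$frame, time = records$time,
                                    resid = records$resid),
                          FUN = mean)
  natm <- stats::aggregate(list(n_atoms = records$atom),
                           by = list(frame = records$frame, resid = records$resid),
                           FUN = length)
  agg <- merge(agg, natm, by = c("frame", "resid"), sort = FALSE)
  agg <- agg[order(agg$frame, agg$resid), ]
  rownames(agg) <- NULL
  class(agg) <- c("residue_stress", "data.frame")
  agg
}

#' Mean square fluctuation of a series
#'
#' MSF = (1/N) sum_t (s_t - mean(s))^2 — population normalization.
#'
#' @param series numeric vector (kbar)
#' @return MSF (kbar^2)
#' @export
stress_msf <- function(series) {
  n <- length(series)
  if (n < 2) stop("MSF requires at least 2 points", call. = FALSE)
  mean((series - mean(series))^2)
}

#' Statistical inefficiency of a time series
#'
#' g = 1 + 2 sum_tau (1 - tau/N) rho(tau), with the normalized
#' autocorrelation rho summed until it first crosses zero, and g clamped to
#' >= 1. The mean of the series then has effective sample size N / g.
#'
#' @param series numeric vector, length >= 10
#' @return g (dimensionless, >= 1)
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 10) stop("statistical inefficiency requires at least 10 points",
                   call. = FALSE)
  s <- series - mean(series)
  c0 <- mean(s * s)
  if (c0 <= 0) {
    warning("zero-variance series: statistical inefficiency defined as 1")
    return(1)
  }
  g <- 1
  for (tau in seq_len(n - 1)) {
    rho <- mean(s[seq_len(n - tau)] * s[seq_len(n - tau) + tau]) / c0
    if (rho <= 0) break
    g <- g + 2 * (1 - tau / n) * rho
  }
  max(1, g)
}

#' Autocorrelation-corrected standard error of the mean
#'
#' sem = sqrt(sample variance * g / N) with g the statistical inefficiency:
#' the plain SEM inflated by the reduced effective sample size of a
#' correlated series.
#'
#' @param series numeric vector, length >= 10
#' @return SEM (kbar)
#' @export
stress_sem <- function(series) {
  n <- length(series)
  g <- statistical_inefficiency(series)
  sqrt(stats::var(series) * g / n)
}

#' Summary statistics of stress series
#'
#' Per key (atom or residue), for one value column: time mean, MSF,
#' statistical inefficiency and SEM.
#'
#' @param records an `atom_stress` or `residue_stress` data.frame
#' @param by key column: `"atom"` or `"resid"`
#' @param value value column to summarize (default `"total"`)
#' @return data.frame of class `stress_summary`: `key`, `mean` (kbar),
#'   `msf` (kbar^2), `sem` (kbar), `g`, `n_frames`
#' @export
stress_summary <- function(records, by = c("resid", "atom"), value = "total") {
  by <- match.arg(by)
  if (!by %in% names(records))
    stop("records have no '", by, "' column", call. = FALSE)
  if (!value %in% names(records))
    stop("records have no '", value, "' column", call. = FALSE)
  keys <- sort(unique(records[[by]]))
  out <- data.frame(key = keys, mean = NA_real_, msf = NA_real_,
                    sem = NA_real_, g = NA_real_, n_frames = NA_integer_)
  for (q in seq_along(keys)) {
    s <- records[[value]][records[[by]] == keys[q]]
    s <- s[order(records$frame[records[[by]] == keys[q]])]
    out$mean[q] <- mean(s)
    out$n_frames[q] <- length(s)
    if (length(s) >= 2) out$msf[q] <- stress_msf(s)
    if (length(s) >= 10) {
      out$g[q] <- statistical_inefficiency(s)
      out$sem[q] <- sqrt(stats::var(s) * out$g[q] / length(s))
    }
  }
  attr(out, "value") <- value
  attr(out, "by") <- by
  class(out) <- c("stress_summary", "data.frame")
  out
}

#' Between-condition stress difference map
#'
#' Per-key differences of two summaries (a minus b) with the SEMs combined
#' in quadrature; MSF differences carry no SEM.
#'
#' @param summary_a,summary_b `stress_summary` objects over identical key
#'   sets
#' @return data.frame: `key`, `delta_mean`, `sem_delta`, `delta_msf`
#' @export
difference_map <- function(summary_a, summary_b) {
  if (!setequal(summary_a$key, summary_b$key)) {
    missing_a <- setdiff(summary_b$key, summary_a$key)
    missing_b <- setdiff(summary_a$key, summary_b$key)
    stop("key sets differ; missing in a: {",
         paste(missing_a, collapse = ","), "}, missing in b: {",
         paste(missing_b, collapse = ","), "}", call. = FALSE)
  }
  b <- summary_b[match(summary_a$key, summary_b$key), ]
  data.frame(key = summary_a$key,
             delta_mean = summary_a$mean - b$mean,
             sem_delta = sqrt(summary_a$sem^2 + b$sem^2),
             delta_msf = summary_a$msf - b$msf)
}
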