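# QIBA diffusion-profile metrics, repeatability/reproducibility
# coefficients, and TOST equivalence testing.
#
# The repeatability constant is 2.77 = 1.96 * sqrt(2): the half-width of the
# 95% interval for the difference of two replicate measurements.

.RC_CONST <- 2.77

#' QIBA conformance tolerances for the diffusion profile
#'
#' Tolerances for |%bias| (%), RC_ST (um2/ms), CV_ST (%), RC_LT (um2/ms)
#' and CV_LT (%).
#' @return named numeric vector.
#' @export
qibaTolerances <- function() {
  c(pct_bias = 3.60, rc_st = 0.015, cv_st = 0.5, rc_lt = 0.065, cv_lt = 2.2)
}

#' QIBA diffusion-profile summary metrics for one vial
#'
#' Computes, from per-scan ADC values organised by session and repeat:
#' \itemize{
#'   \item \code{pct_bias} = 100 * (grand mean - truth) / truth;
#'   \item short-term: wSD = sqrt(mean over sessions of the within-session
#'     variance), RC_ST = 2.77 * wSD (um2/ms), CV_ST = 100 * wSD / grand
#'     mean;
#'   \item long-term: SD_LT = SD of the per-session means, RC_LT = 2.77 *
#'     SD_LT (um2/ms), CV_LT = 100 * SD_LT / grand mean.
#' }
#' Long-term metrics are NA with a single session. Conformance flags
#' compare each metric against [qibaTolerances()] (|%bias| for the bias).
#'
#' @param adc per-scan ADC values, um2/s.
#' @param session session identifier per scan.
#' @param truth reference ADC, um2/s.
#' @return list with the five metrics, `grand_mean`, and `conformant`
#'   (named logical).
#' @export
qibaSummary <- function(adc, session, truth) {
  if (length(adc) != length(session))
    stop("adc and session must have equal length")
  gm <- mean(adc)
  pct_bias <- 100 * (gm - truth) / truth
  by_sess <- split(adc, session)
  with_var <- vapply(by_sess, function(x)
    if (length(x) >= 2L) stats::var(x) else NA_real_, numeric(1))
  wSD <- if (all(is.na(with_var))) NA_real_
         else sqrt(mean(with_var, na.rm = TRUE))
  rc_st <- adcUm2sToUm2ms(.RC_CONST * wSD)
  cv_st <- 100 * wSD / gm
  if (length(by_sess) >= 2L) {
    sd_lt <- stats::sd(vapply(by_sess, mean, numeric(1)))
    rc_lt <- adcUm2sToUm2ms(.RC_CONST * sd_lt)
    cv_lt <- 100 * sd_lt / gm
  } else {
    rc_lt <- NA_real_
    cv_lt <- NA_real_
  }
  tol <- qibaTolerances()
  metrics <- c(pct_bias = pct_bias, rc_st = rc_st, cv_st = cv_st,
               rc_lt = rc_lt, cv_lt = cv_lt)
  conf <- c(abs(metrics["pct_bias"]) <= tol["pct_bias"],
            metrics[-1] <= tol[-1])
  names(conf) <- names(tol)
  c(as.list(metrics), list(grand_mean = gm, conformant = conf))
}

#' Short-term repeatability coefficient (%RC)
#'
#' Per institute and vial: \code{\%RC = 100 * 2.77 * SD(repeats) /
#' mean(repeats)}. Institutes with fewer than 2 repeats for a vial are
#' excluded and reported. The summary aggregates per-vial values across
#' institutes and vials (median and range).
#'
#' @param adc ADC values, um2/s.
#' @param institute institute/site identifier per value.
#' @param vial vial label per value.
#' @return list: `per_vial` data.frame (institute, vial, n, pct_rc),
#'   `median`, `range`, `excluded` (institutes dropped for lack of
#'   repeats).
#' @examples
#' pctRC(c(1090, 1110), rep("A", 2), rep("v", 2))$per_vial$pct_rc  # 3.56
#' @export
pctRC <- function(adc, institute, vial) {
  df <- data.frame(adc = adc, institute = as.character(institute),
                   vial = as.character(vial))
  grp <- split(df, list(df$institute, df$vial), drop = TRUE)
  rows <- lapply(grp, function(g) {
    data.frame(institute = g$institute[1], vial = g$vial[1],
               n = nrow(g),
               pct_rc = if (nrow(g) >= 2L)
                 100 * .RC_CONST * stats::sd(g$adc) / mean(g$adc)
               else NA_real_)
  })
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  excluded <- unique(per$institute[is.na(per$pct_rc)])
  ok <- per[!is.na(per$pct_rc), ]
  if (!nrow(ok)) stop("no institute has >= 2 repeats")
  list(per_vial = per, median = stats::median(ok$pct_rc),
       range = range(ok$pct_rc), excluded = excluded)
}

#' Inter-institutional reproducibility coefficient (%RDC)
#'
#' Per vial, across institutes' first-repeat ADC values:
#' \code{\%RDC = 100 * 2.77 * SD / mean}. Needs at least 3 institutes.
#'
#' @param adc first-repeat ADC values, um2/s.
#' @param institute institute identifier per value.
#' @param vial vial label per value.
#' @return list: `per_vial` data.frame (vial, n_institutes, pct_rdc),
#'   `median`, `range`.
#' @examples
#' pctRDC(c(1000, 1100, 1200), c("A", "B", "C"), rep("v", 3))$median  # 25.2
#' @export
pctRDC <- function(adc, institute, vial) {
  df <- data.frame(adc = adc, institute = as.character(institute),
                   vial = as.character(vial))
  grp <- split(df, df$vial)
  rows <- lapply(grp, function(g) {
    if (anyDuplicated(g$institute))
      stop("one value per institute expected (first repeat only)")
    if (nrow(g) < 3L)
      stop("%RDC needs at least 3 institutes (vial ", g$vial[1], ")")
    data.frame(vial = g$vial[1], n_institutes = nrow(g),
               pct_rdc = 100 * .RC_CONST * stats::sd(g$adc) / mean(g$adc))
  })
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_vial = per, median = stats::median(per$pct_rdc),
       range = range(per$pct_rdc))
}

# One-sided Wilcoxon signed-rank p-value with Pratt handling of zeros:
# zeros are ranked with the rest, then dropped; the null distribution of
# W+ (sum of ranks of positives) is exact for m <= 25 via dynamic
# programming over doubled midranks, else a normal approximation with
# continuity correction.
.signed_rank_p <- function(x, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  rk <- rank(abs(x))          # zeros included in the ranking (Pratt)
  nz <- x != 0
  r <- rk[nz]
  w <- sum(r[x[nz] > 0])
  m <- length(r)
  if (m == 0L) return(1)
  if (m <= 25L) {
    r2 <- as.integer(round(2 * r))  # doubled midranks are integers
    total <- sum(r2)
    # distribution of 2*W+ over subsets of r2
    dp <- numeric(total + 1L)
    dp[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dp[seq_len(total + 1L - ri)])
      dp <- dp + shifted
    }
    dp <- dp / 2^m
    w2 <- round(2 * w)
    p_ge <- sum(dp[(w2 + 1L):(total + 1L)])
    p_le <- sum(dp[seq_len(w2 + 1L)])
  } else {
    mu <- sum(r) / 2
    sg <- sqrt(sum(r^2) / 4)
    p_ge <- stats::pnorm((w - 0.5 - mu) / sg, lower.tail = FALSE)
    p_le <- stats::pnorm((w + 0.5 - mu) / sg)
  }
  if (alternative == "greater") p_ge else p_le
}

#' TOST equivalence test with paired Wilcoxon signed-rank tests
#'
#' Two one-sided signed-rank tests at tolerance +/- delta: the lower test
#' rejects H0 "median difference <= -delta" (signed-rank on diffs + delta,
#' alternative greater), the upper test rejects H0 "median difference >=
#' +delta" (signed-rank on delta - diffs, alternative greater). The TOST
#' p-value is the larger of the two; equivalence is declared at p < 0.05.
#'
#' @param diffs paired per-image ADC differences, um2/s.
#' @param delta equivalence tolerance, um2/s (> 0).
#' @return list: `p_tost`, `p_lower`, `p_upper`, `delta`, `n`,
#'   `equivalent`, `stars` ("*", "**", "***" at 0.05/0.01/0.001, else "").
#' @export
tostWilcoxon <- function(diffs, delta) {
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("delta must be a single positive tolerance")
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 6L)
    warning("fewer than 6 paired differences: TOST cannot reach p < 0.05")
  if (all(abs(abs(diffs) - delta) < 1e-12))
    warning("all differences coincide with +/-delta: degenerate TOST")
  p_lower <- .signed_rank_p(diffs + delta, "greater")
  p_upper <- .signed_rank_p(delta - diffs, "greater")
  p <- max(p_lower, p_upper)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else ""
  list(p_tost = p, p_lower = p_lower, p_upper = p_upper, delta = delta,
       n = n, equivalent = p < 0.05, stars = stars)
}

#' Default descending tolerance grid for the minimal-tolerance search
#' @return numeric vector: 50..1 by 1, then 0.9..0.1 by 0.1, then
#'   0.09..0.01 by 0.01 (um2/s).
#' @export
equivalenceToleranceGrid <- function() {
  c(seq(50, 1, by = -1), seq(0.9, 0.1, by = -0.1),
    seq(0.09, 0.01, by = -0.01))
}

#' Minimal tolerance at which all vials are significantly equivalent
#'
#' Descends the tolerance grid and returns the smallest delta for which
#' [tostWilcoxon()] gives p < 0.05 in every vial. If even the largest grid
#' value fails, `delta` is NA ("not equivalent at max grid").
#'
#' @param diffsPerVial named list of paired-difference vectors (um2/s), one
#'   per vial.
#' @param grid descending tolerance grid (default
#'   [equivalenceToleranceGrid()]).
#' @param alpha significance level (default 0.05).
#' @return list: `delta` (um2/s or NA), `achieved` (logical), `p_per_vial`
#'   (at the returned delta, or at the max grid value when not achieved).
#' @export
minimalEquivalenceTolerance <- function(diffsPerVial,
                                        grid = equivalenceToleranceGrid(),
                                        alpha = 0.05) {
  grid <- sort(grid, decreasing = TRUE)
  p_at <- function(delta) vapply(diffsPerVial, function(d)
    suppressWarnings(tostWilcoxon(d, delta)$p_tost), numeric(1))
  best <- NA_real_
  best_p <- p_at(grid[1])
  if (any(best_p >= alpha))
    return(list(delta = NA_real_, achieved = FALSE, p_per_vial = best_p,
                message = "not equivalent at max grid"))
  for (delta in grid) {
    p <- p_at(delta)
    if (all(p < alpha)) {
      best <- delta
      best_p <- p
    } else break
  }
  list(delta = best, achieved = TRUE, p_per_vial = best_p)
}
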