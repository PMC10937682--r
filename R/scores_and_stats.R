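# Cohort and per-cell statistics: mean-z-score gene-signature scores,
# TMB median split, quartile stratification, Pearson correlation with an
# exact t-based two-tailed p-value, Kaplan-Meier estimation and the
# Mantel-Cox log-rank test, plus the caliper tumour-volume formula.
# No multiple-testing correction is applied anywhere.

# Gene signatures used for the cohort analysis (effector CD8 T cells and
# cross-presenting cDC1), as gene-symbol vectors.

#' Built-in gene signatures
#'
#' `cdc1`: Batf3, Irf8, Thbd, Clec9a, Xcr1 — markers of conventional
#' type 1 dendritic cells. `cd8_effector`: Cd8a, Cd8b, Ifng, Prf1 —
#' effector CD8 T-cell markers.
#'
#' @param name `"cdc1"` or `"cd8_effector"`.
#' @return List with `name` and `genes`.
#' @export
signature_def <- function(name = c("cdc1", "cd8_effector")) {
  name <- match.arg(name)
  genes <- switch(name,
                  cdc1 = c("BATF3", "IRF8", "THBD", "CLEC9A", "XCR1"),
                  cd8_effector = c("CD8A", "CD8B", "IFNG", "PRF1"))
  list(name = name, genes = genes)
}

#' Score entities by the unweighted mean over a gene signature
#'
#' The same operation serves cohort samples (z-scores relative to all
#' samples) and single cells (normalized expression): the score is the
#' mean of the per-gene values over the signature genes present in the
#' matrix. Missing genes are dropped with one warning listing them; a
#' signature with no gene present is an error.
#'
#' @param values Numeric matrix or data frame, entities in rows and genes
#'   in columns (column names are gene symbols; matching is
#'   case-insensitive).
#' @param signature A signature from [signature_def()], or a character
#'   vector of gene symbols.
#' @return Named numeric vector of scores, one per row of `values`.
#' @export
signature_score <- function(values, signature) {
  genes <- if (is.list(signature)) signature$genes else signature
  stopifnot(length(genes) > 0, !anyDuplicated(genes))
  values <- as.matrix(values)
  idx <- match(toupper(genes), toupper(colnames(values)))
  if (all(is.na(idx))) {
    stopf("none of the signature genes (%s) are present",
          paste(genes, collapse = ", "))
  }
  if (anyNA(idx)) {
    warnf("signature gene(s) missing and dropped: %s",
          paste(genes[is.na(idx)], collapse = ", "))
  }
  sub <- values[, idx[!is.na(idx)], drop = FALSE]
  setNames(rowMeans(sub), rownames(values))
}

#' Split samples at the median
#'
#' `high` means strictly above the median; ties go to `low` (value <=
#' median). The median is the standard midpoint definition.
#'
#' @param x Numeric vector (n >= 2; all-identical values are a
#'   degenerate split and an error).
#' @return Factor with levels `low`, `high`, same names as `x`.
#' @export
median_split <- function(x) {
  stopifnot(length(x) >= 2L)
  if (length(unique(x)) == 1L) stopf("degenerate median split: all values identical")
  m <- median(x)
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

#' Assign bottom/middle/top quartile groups
#'
#' `bottom` is scores at or below the first quartile, `top` at or above
#' the third; quartiles use the linear-interpolation convention
#' (`quantile(type = 7)`, the most common default). Boundary membership
#' is inclusive.
#'
#' @param x Numeric vector, n >= 4.
#' @return Factor with levels `bottom`, `middle`, `top`.
#' @export
quartile_groups <- function(x) {
  if (length(x) < 4L) stopf("quartile stratification needs n >= 4")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] >= q[2]) stopf("degenerate quartiles: Q1 >= Q3")
  factor(ifelse(x <= q[1], "bottom", ifelse(x >= q[2], "top", "middle")),
         levels = c("bottom", "middle", "top"))
}

#' Pearson correlation with a two-tailed t-based p-value
#'
#' Standard product-moment correlation; the p-value comes from the exact
#' t transform with n - 2 degrees of freedom, not a normal
#' approximation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, both with
#'   non-zero variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stopf("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance in x or y")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Mantel-Cox log-rank test for two survival curves
#'
#' The standard one-degree-of-freedom log-rank statistic under right
#' censoring, with the usual hypergeometric variance at tied event
#' times.
#'
#' @param time_a,event_a Times and event indicators (1 = event,
#'   0 = censored) for group A.
#' @param time_b,event_b Same for group B.
#' @return List with `chi2`, `p`, `obs_a`, `exp_a`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  if (sum(event_a) + sum(event_b) == 0L) {
    stopf("log-rank test needs at least one event")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  if (any(time < 0)) stopf("negative survival times")
  etimes <- sort(unique(time[event == 1L]))
  o_minus_e <- 0; v <- 0; obs_a <- 0; exp_a <- 0
  for (t in etimes) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp_a)
    dj <- sum(event == 1L & time == t)
    d1j <- sum(event == 1L & time == t & grp_a)
    e1j <- dj * n1j / nj
    obs_a <- obs_a + d1j
    exp_a <- exp_a + e1j
    o_minus_e <- o_minus_e + (d1j - e1j)
    if (nj > 1L) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       obs_a = obs_a, exp_a = exp_a)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param time Non-negative observation times.
#' @param event Event indicators (1 = event, 0 = right-censored).
#' @return Data frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv` (the step value from that time
#'   onwards). `S(t) = 1` before the first event.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stopf("negative survival times")
  event <- as.integer(event)
  etimes <- sort(unique(time[event == 1L]))
  surv <- 1
  rows <- lapply(etimes, function(t) {
    n_risk <- sum(time >= t)
    n_event <- sum(time == t & event == 1L)
    surv <<- surv * (1 - n_event / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = n_event, surv = surv)
  })
  if (length(rows) == 0L) {
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), surv = numeric()))
  }
  do.call(rbind, rows)
}

#' Tumour volume from caliper measurements
#'
#' `V = d^2 * D / 2`, with `d` the minor and `D` the major tumour axis
#' (mm); the result is in cubic millimetres.
#'
#' @param d Minor axis (mm), `0 < d <= D`.
#' @param D Major axis (mm).
#' @return Volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(d, D) {
  if (any(d <= 0) || any(D <= 0)) stopf("axes must be positive")
  if (any(d > D)) stopf("minor axis d exceeds major axis D")
  d^2 * D / 2
}

#' Read a cohort table
#'
#' @param path TSV with columns `sample_id`, `tmb`, `time_months`,
#'   `event`, then one column per gene (expression z-scores).
#' @return Data frame with those columns; gene columns are everything
#'   after the first four.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "tmb", "time_months", "event")
  if (!all(need %in% names(df))) {
    stopf("cohort table %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  df
}
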