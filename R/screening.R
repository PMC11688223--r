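# Stationarity and artifact screening of interval sequences.

#' Wald-Wolfowitz runs test for serial dependence
#'
#' Dichotomizes the interval sequence around its sample mean (values exactly
#' equal to the mean are dropped), counts runs, and compares the count with
#' its null moments under exchangeability using the normal approximation.  A
#' stationary renewal record should pass; trends, slow drifts and strongly
#' alternating patterns produce large |z| and small p.
#'
#' @param x intervals (ms) or an `"isi_sequence"`; at least 10 values, not
#'   all identical.
#' @param alpha significance level used to set `passed`.
#' @return list with `runs`, `n_above`, `n_below`, `runs_z`, `runs_p`
#'   (two-sided), `passed`, and `degenerate` (all values on one side of the
#'   mean, in which case the record fails with reason "degenerate").
#' @export
runs_test <- function(x, alpha = 0.05) {
  v <- .sample_intervals(x)
  if (length(v) < 10) stop("runs test needs at least 10 intervals")
  if (length(unique(v)) == 1L) stop("runs test undefined for constant intervals")
  m <- mean(v)
  s <- sign(v - m)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) {
    return(list(runs = 1L, n_above = n1, n_below = n2,
                runs_z = NA_real_, runs_p = NA_real_,
                passed = FALSE, degenerate = TRUE))
  }
  r <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  e_r <- 1 + 2 * n1 * n2 / n
  v_r <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (r - e_r) / sqrt(v_r)
  p <- 2 * stats::pnorm(-abs(z))
  list(runs = r, n_above = n1, n_below = n2,
       runs_z = z, runs_p = p, passed = p >= alpha, degenerate = FALSE)
}

#' Screen a collection of records for stationarity and artifacts
#'
#' Applies, in order: a minimum-size screen (at least 10 intervals), a
#' degeneracy screen (zero variance or all intervals on one side of the
#' mean), an artifact screen (longest interval exceeding 10 times the 99th
#' percentile, a reproducible surrogate for visual outlier inspection), and
#' the runs test at level `alpha`.
#'
#' @param records list of `"spike_train_record"` or `"isi_sequence"` objects.
#' @param alpha runs-test significance level.
#' @return list with `kept` (the surviving `"isi_sequence"` objects) and
#'   `report`, a data frame with one row per input record: `record_id`, `n`,
#'   `mean_ms`, `sd_ms`, `cv`, `skewness`, `runs_z`, `runs_p`, `passed`,
#'   `reason` ("" for kept records).
#' @export
screen_records <- function(records, alpha = 0.05) {
  rows <- vector("list", length(records))
  kept <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    isi <- if (inherits(rec, "isi_sequence")) rec else intervals_from_spikes(rec)
    v <- isi$intervals
    st <- if (length(v) >= 2) summary_stats(v) else
      list(mean = NA_real_, sd = NA_real_, cv = NA_real_,
           skewness = NA_real_, n = length(v))
    reason <- ""
    rz <- NA_real_
    rp <- NA_real_
    if (length(v) < 10) {
      reason <- "too_few"
    } else if (length(unique(v)) == 1L) {
      reason <- "degenerate"
    } else if (max(v) > 10 * stats::quantile(v, 0.99, names = FALSE)) {
      reason <- "artifact"
    } else {
      rt <- runs_test(v, alpha = alpha)
      rz <- rt$runs_z
      rp <- rt$runs_p
      if (rt$degenerate) {
        reason <- "degenerate"
      } else if (!rt$passed) {
        reason <- "nonstationary"
      }
    }
    rows[[i]] <- data.frame(record_id = isi$record_id, n = st$n,
                            mean_ms = st$mean, sd_ms = st$sd, cv = st$cv,
                            skewness = st$skewness,
                            runs_z = rz, runs_p = rp,
                            passed = reason == "", reason = reason,
                            stringsAsFactors = FALSE)
    if (reason == "") kept[[length(kept) + 1L]] <- isi
  }
  report <- do.call(rbind, rows)
  if (is.null(report)) {
    report <- data.frame(record_id = character(), n = integer(),
                         mean_ms = numeric(), sd_ms = numeric(),
                         cv = numeric(), skewness = numeric(),
                         runs_z = numeric(), runs_p = numeric(),
                         passed = logical(), reason = character(),
                         stringsAsFactors = FALSE)
  }
  list(kept = kept, report = report)
}
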