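#' Round half away from zero
#'
#' Reporting convention for removal rates and rate increases (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Validate an abundance-series table
#'
#' Long-format flow-cytometry-style counts: one row per treatment,
#' replicate, time and target. Counts must be non-negative, every
#' (treatment, replicate, target) series must include time 0, and replicates
#' of a treatment share a time grid (missing values allowed).
#'
#' @param df data.frame with columns `treatment, replicate, time_days,
#'   target, count_per_ml`
#' @return the validated data.frame (invisibly classed `abundance_series`)
#' @export
as_abundance_series <- function(df) {
  need <- c("treatment", "replicate", "time_days", "target", "count_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$count_per_ml < 0, na.rm = TRUE)) stop("counts must be non-negative")
  key <- interaction(df$treatment, df$replicate, df$target, drop = TRUE)
  has0 <- tapply(df$time_days, key, function(t) any(t == 0))
  if (any(!has0)) stop("every replicate series must include time 0")
  class(df) <- c("abundance_series", "data.frame")
  df
}

#' Percent reduction in abundance since time zero
#'
#' Per-replicate percent reduction `100 * (1 - count(t) / count(0))`,
#' averaged across the replicates of each treatment; the standard deviation
#' across replicates is reported when n >= 2. Replicates with a zero count
#' at time 0 are excluded (counted in `n_excluded`).
#'
#' @param series abundance table (see [as_abundance_series()])
#' @param at time (days) at which to evaluate the reduction
#' @param target which counts to use (`"virus"` default)
#' @return data.frame (one row per treatment) with columns `treatment`,
#'   `time_days`, `reduction_mean`, `reduction_sd`, `daily_rate`,
#'   `n_replicates`, `n_excluded`
#' @export
percent_reduction <- function(series, at, target = "virus") {
  series <- as_abundance_series(as.data.frame(series))
  d <- series[series$target == target, , drop = FALSE]
  if (!nrow(d)) stop("no rows for target '", target, "'")
  out <- lapply(split(d, d$treatment, drop = TRUE), function(g) {
    reds <- c(); excl <- 0L
    for (rep in unique(g$replicate)) {
      gr <- g[g$replicate == rep, ]
      c0 <- gr$count_per_ml[gr$time_days == 0]
      ct <- gr$count_per_ml[gr$time_days == at]
      if (!length(c0) || !length(ct) || is.na(c0[1L]) || is.na(ct[1L])) next
      if (c0[1L] == 0) {
        warning("replicate '", rep, "' excluded: zero count at time 0")
        excl <- excl + 1L
        next
      }
      reds <- c(reds, 100 * (1 - ct[1L] / c0[1L]))
    }
    if (!length(reds)) stop("no usable replicates at time ", at)
    data.frame(treatment = g$treatment[1L], time_days = at,
               reduction_mean = mean(reds),
               reduction_sd = if (length(reds) >= 2L) stats::sd(reds) else NA_real_,
               daily_rate = daily_removal_rate(mean(reds), at, round_result = FALSE),
               n_replicates = length(reds), n_excluded = excl)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linear daily removal rate
#'
#' `reduction / elapsed`, the constant daily rate that would produce the
#' observed percent reduction linearly. The reporting convention rounds to
#' one decimal, half away from zero; set `round_result = FALSE` to keep the
#' unrounded rate (required as input to [rate_increase()]).
#'
#' @param reduction percent reduction
#' @param elapsed days elapsed (> 0)
#' @param round_result apply the reporting rounding (default TRUE)
#' @return percent per day
#' @export
daily_removal_rate <- function(reduction, elapsed, round_result = TRUE) {
  if (any(elapsed <= 0)) stop("elapsed must be > 0")
  r <- reduction / elapsed
  if (isTRUE(round_result)) round_half_away(r, 1) else r
}

#' Relative increase in removal rate
#'
#' `100 * (rate_treatment - rate_reference) / rate_reference`. Unrounded
#' rates must be supplied; the reported value is rounded to the nearest
#' integer (half away from zero) unless `round_result = FALSE`.
#'
#' @param rate_treatment,rate_reference removal rates (% per day);
#'   `rate_reference` must be > 0
#' @param round_result apply integer reporting rounding
#' @return percent increase
#' @export
rate_increase <- function(rate_treatment, rate_reference, round_result = TRUE) {
  if (any(rate_reference <= 0)) stop("rate_reference must be > 0")
  x <- 100 * (rate_treatment - rate_reference) / rate_reference
  if (isTRUE(round_result)) round_half_away(x, 0) else x
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test assuming unequal variances, with the
#' Welch--Satterthwaite degrees of freedom (wraps [stats::t.test()]).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2; at least
#'   one must have nonzero variance
#' @return list with `t`, `df`, `p`
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs n >= 2")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("both samples have zero variance; t statistic undefined")
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# exact null distribution of the signed-rank statistic W+ for given ranks:
# P(W+ = s) via the generating function prod_i (1 + x^r_i) / 2^n. Ranks are
# mid-ranks, so work on doubled (integer) ranks.
signed_rank_exact_p <- function(W, ranks) {
  r2 <- round(2 * ranks)
  total <- sum(r2)
  pmf <- numeric(total + 1L)  # index s+1 for statistic value s (doubled scale)
  pmf[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  W2 <- round(2 * W)
  # two-sided: double the smaller tail (capped at 1)
  lo <- sum(pmf[seq_len(W2 + 1L)])
  hi <- sum(pmf[(W2 + 1L):(total + 1L)])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences. Zero
#' differences are dropped; ties receive mid-ranks. For n <= 25 (after
#' dropping zeros) the exact null distribution of W+ is computed by
#' generating-function convolution (valid with mid-rank ties); above that, a
#' normal approximation with continuity correction and the usual tie
#' correction to the variance is used.
#'
#' @param differences numeric vector of paired differences; n >= 5 required
#'   after removing zeros
#' @param exact_max largest n for which the exact distribution is used
#' @return list with `W` (sum of positive ranks), `n` (nonzero differences),
#'   `p` (two-sided) and `method`
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  d <- differences[!is.na(differences)]
  if (all(d == 0)) stop("all differences are zero")
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop("need at least 5 nonzero differences (got ", n, ")")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(W, rk)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = W, n = n, p = p, method = method)
}

#' Treatment comparison table
#'
#' Welch-tests counts between two treatments at each shared time point.
#'
#' @param series abundance table (see [as_abundance_series()])
#' @param treatment_a,treatment_b treatment labels to compare
#' @param target which counts to compare
#' @return data.frame with columns `treatment_a, treatment_b, time_days, t,
#'   df, p`
#' @export
compare_treatments <- function(series, treatment_a, treatment_b,
                               target = "virus") {
  series <- as_abundance_series(as.data.frame(series))
  d <- series[series$target == target, ]
  a <- d[d$treatment == treatment_a, ]
  b <- d[d$treatment == treatment_b, ]
  times <- sort(intersect(unique(a$time_days), unique(b$time_days)))
  rows <- lapply(times, function(tt) {
    xa <- a$count_per_ml[a$time_days == tt]
    xb <- b$count_per_ml[b$time_days == tt]
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    if (stats::var(xa) == 0 && stats::var(xb) == 0) return(NULL)
    ht <- welch_t_test(xa, xb)
    data.frame(treatment_a = treatment_a, treatment_b = treatment_b,
               time_days = tt, t = ht$t, df = ht$df, p = ht$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(treatment_a = character(0), treatment_b = character(0),
                      time_days = numeric(0), t = numeric(0), df = numeric(0),
                      p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Read / write abundance-series CSV
#'
#' Columns: `treatment, replicate, time_days, target, count_per_ml`.
#' @param path file path
#' @param series abundance table
#' @export
read_abundance_csv <- function(path) {
  as_abundance_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_abundance_csv
#' @export
write_abundance_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
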