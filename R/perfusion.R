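#' Laser Doppler flowmetry trace
#'
#' A tidy trace: strictly increasing time in seconds and perfusion in
#' arbitrary perfusion units (PU), with specimen metadata.
#'
#' @param time_s numeric, strictly increasing.
#' @param perfusion_pu numeric, same length.
#' @param animal,limb,week,segment metadata (limb is `"affected"` or
#'   `"unaffected"` in the study design).
#' @param check_positive warn on negative perfusion values (default TRUE).
#' @return a data.frame of class `LDFTrace`.
#' @export
ldf_trace <- function(time_s, perfusion_pu, animal = NA, limb = NA,
                      week = NA, segment = NA, check_positive = TRUE) {
  stopifnot(length(time_s) == length(perfusion_pu))
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("time must be strictly increasing")
  if (check_positive && any(perfusion_pu < 0, na.rm = TRUE))
    warning("negative perfusion values in trace")
  structure(data.frame(time_s = time_s, perfusion_pu = perfusion_pu),
            animal = animal, limb = limb, week = week, segment = segment,
            class = c("LDFTrace", "data.frame"))
}

#' Duration-weighted mean perfusion over repeated measurements
#'
#' Each weekly perfusion value for a bone is the weighted mean of its
#' repeated 30-second probe placements, weighted by the valid recorded
#' duration of each segment (number of valid samples times the sampling
#' interval). Empty segments are dropped with a warning.
#'
#' @param segments list of [ldf_trace()]s from the same bone and week.
#' @return an object of class `PerfusionRecord`: `animal`, `limb`, `week`,
#'   `mean_pu`, `n_segments`, `segment_durations_s`, `segment_means_pu`.
#' @export
weighted_mean_perfusion <- function(segments) {
  if (length(segments) == 0) stop("no segments supplied")
  ok <- vapply(segments, function(s) {
    sum(is.finite(s$perfusion_pu)) > 0
  }, logical(1))
  if (!any(ok)) stop("all segments are empty")
  if (any(!ok)) warning(sprintf("%d empty segment(s) excluded", sum(!ok)))
  segments <- segments[ok]
  dur <- vapply(segments, function(s) {
    valid <- is.finite(s$perfusion_pu)
    dt <- if (nrow(s) > 1) median(diff(s$time_s)) else 1
    sum(valid) * dt
  }, numeric(1))
  mns <- vapply(segments, function(s) mean(s$perfusion_pu, na.rm = TRUE),
                numeric(1))
  s1 <- segments[[1]]
  structure(list(animal = attr(s1, "animal"), limb = attr(s1, "limb"),
                 week = attr(s1, "week"),
                 mean_pu = sum(dur * mns) / sum(dur),
                 n_segments = length(segments),
                 segment_durations_s = dur,
                 segment_means_pu = mns),
            class = "PerfusionRecord")
}

#' @export
print.PerfusionRecord <- function(x, ...) {
  cat(sprintf("PerfusionRecord: %.3f PU (weighted mean of %d segments)\n",
              x$mean_pu, x$n_segments))
  invisible(x)
}

#' Slope of an LDF trace
#'
#' Ordinary-least-squares slope of perfusion on time over the full trace
#' (used on the 30-minute intra-operative measurement to check stability),
#' reported in PU per minute with its standard error.
#'
#' @param trace an [ldf_trace()].
#' @return list with `slope_pu_per_min`, `se_pu_per_min`, `n`.
#' @export
trace_slope <- function(trace) {
  if (nrow(trace) < 3) stop("need at least 3 samples")
  if (var(trace$time_s) == 0) stop("constant time vector")
  fit <- lm(perfusion_pu ~ time_s, data = trace)
  n <- nrow(trace)
  sxx <- sum((trace$time_s - mean(trace$time_s))^2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
  list(slope_pu_per_min = unname(coef(fit)[2]) * 60,
       se_pu_per_min = se * 60,
       n = n)
}

#' Test whether per-animal trace slopes differ from zero
#'
#' Stability check for the intra-operative perfusion recording: under a
#' stable measurement the slope of each animal's trace should be zero. Either
#' a one-sample t test or a Wilcoxon signed-rank test against zero. The
#' signed-rank p value is computed by exhaustive enumeration of all 2^n sign
#' assignments for n <= 15 (handling ties in the absolute values by
#' midranks; zero slopes are dropped by the standard convention, and a sample
#' of all zeros returns p = 1); larger samples use the normal approximation.
#'
#' @param slopes numeric vector of per-animal slopes (PU/min).
#' @param method `"t"` or `"signed_rank"`.
#' @return list with `statistic`, `p_value`, `method`, `n`.
#' @export
slope_stability_test <- function(slopes, method = c("t", "signed_rank")) {
  method <- match.arg(method)
  if (length(slopes) < 2) stop("need at least 2 slopes")
  if (method == "t") {
    if (var(slopes) == 0)
      stop("zero variance: the t statistic is undefined for identical slopes")
    ht <- t.test(slopes, mu = 0)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "one-sample t", n = length(slopes)))
  }
  x <- slopes[slopes != 0]
  n <- length(x)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, method = "signed rank",
                n = 0L))
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  if (n <= 15) {
    # exhaustive enumeration of sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    ple <- mean(vs <= v + 1e-9)
    pge <- mean(vs >= v - 1e-9)
    p <- min(1, 2 * min(ple, pge))
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (v - mu) / sig
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, p_value = p, method = "signed rank", n = n)
}

#' Percent difference between two values
#'
#' `100 * (a - b) / b`: the relative change of `a` with respect to the
#' reference `b`.
#'
#' @param a,b numeric.
#' @return percent difference.
#' @export
percent_difference <- function(a, b) 100 * (a - b) / b

#' Descriptive summary of perfusion records by group
#'
#' Per-cell mean, SD and n over a tidy table of perfusion records. Cells of
#' the full factor grid that contain no data are reported with `n = 0` and
#' `NA` summaries (missing, not zero).
#'
#' @param records data.frame with a `mean_pu` column and grouping columns.
#' @param by character vector of grouping column names.
#' @return tidy data.frame with one row per cell of the grouping grid.
#' @export
group_summary <- function(records, by) {
  stopifnot(all(by %in% names(records)), "mean_pu" %in% names(records))
  agg <- aggregate(records$mean_pu, records[by], function(v)
    c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(agg[by], mean_pu = agg$x[, "mean"],
                    sd_pu = agg$x[, "sd"], n = agg$x[, "n"])
  grid <- do.call(expand.grid,
                  c(lapply(records[by], function(col) sort(unique(col))),
                    list(stringsAsFactors = FALSE)))
  names(grid) <- by
  out <- merge(grid, out, by = by, all.x = TRUE, sort = TRUE)
  out$n[is.na(out$n)] <- 0
  out
}
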