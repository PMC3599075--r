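# Sample quality control: Dixon's Q outlier test with Monte-Carlo critical
# values, multi-criteria outlier scans, and the Bioanalyzer 50%-area mean
# fragment size.

# cache of simulated null Q distributions, keyed by (n, side, seed, n_sim)
.dixon_cache <- new.env(parent = emptyenv())

.dixon_stat <- function(x, side) {
  s <- sort(x)
  n <- length(s)
  rng <- s[n] - s[1]
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  switch(side,
         low = list(statistic = q_low, suspect = 1L),
         high = list(statistic = q_high, suspect = n),
         two_sided = if (q_high >= q_low) list(statistic = q_high, suspect = n)
                     else list(statistic = q_low, suspect = 1L))
}

.dixon_null <- function(n, side, seed = 1L, n_sim = 1e5) {
  key <- paste(n, side, seed, n_sim, sep = "|")
  if (!is.null(.dixon_cache[[key]])) return(.dixon_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- matrix(stats::rnorm(n_sim * n), n_sim, n)
  cols <- lapply(seq_len(n), function(j) x[, j])
  s1 <- do.call(pmin, cols)
  sn <- do.call(pmax, cols)
  x2 <- x; x2[x == s1] <- Inf          # mask the row minima
  s2 <- do.call(pmin, lapply(seq_len(n), function(j) x2[, j]))
  x3 <- x; x3[x == sn] <- -Inf         # mask the row maxima
  sn1 <- do.call(pmax, lapply(seq_len(n), function(j) x3[, j]))
  rng <- sn - s1
  q_low <- (s2 - s1) / rng
  q_high <- (sn - sn1) / rng
  q <- switch(side, low = q_low, high = q_high, two_sided = pmax(q_low, q_high))
  .dixon_cache[[key]] <- q
  q
}

#' Monte-Carlo critical value for Dixon's Q
#'
#' Simulates the null distribution of the r10 gap-to-range statistic under
#' i.i.d. standard-normal samples of size `n` and returns its
#' `1 - alpha` quantile.  Results are cached by `(n, side, seed, n_sim)`,
#' so repeated calls are cheap and identical.
#'
#' @param n sample size, 3..30.
#' @param alpha significance level; `alpha >= 1` gives critical value 0.
#' @param side which extreme is tested; `two_sided` uses the larger of the
#'   two one-sided statistics (the null is simulated accordingly, so the
#'   test keeps its nominal level).
#' @param seed seed of the null simulation.
#' @param n_sim number of null draws (>= 1e5 recommended).
#' @return the critical value.
#' @export
dixon_critical_value <- function(n, alpha = 0.05,
                                 side = c("two_sided", "low", "high"),
                                 seed = 1L, n_sim = 1e5) {
  side <- match.arg(side)
  if (n < 3 || n > 30) stop("dixon_critical_value: n must be in 3..30", call. = FALSE)
  if (alpha >= 1) return(0)
  unname(stats::quantile(.dixon_null(n, side, seed, n_sim), 1 - alpha))
}

#' Dixon's Q test for a single outlier in a small sample
#'
#' Classic r10 statistic: the gap between the suspect extreme value and its
#' nearest neighbour, divided by the sample range.  The critical value and
#' Monte-Carlo p-value come from a simulated standard-normal null (see
#' [dixon_critical_value()]); the statistic itself is location- and
#' scale-invariant, so the null needs no standardization.
#'
#' @param values numeric vector, 3 <= length <= 30, not all equal.
#' @param side `"two_sided"` (default) tests the more extreme end;
#'   `"low"`/`"high"` test a specific end.
#' @param alpha significance level.
#' @param seed,n_sim Monte-Carlo null parameters.
#' @return a `QResult` list: `statistic`, `suspect_index` (position in the
#'   input vector), `n`, `critical_value`, `p_value`, `is_outlier`.
#' @export
dixon_q <- function(values, side = c("two_sided", "low", "high"),
                    alpha = 0.05, seed = 1L, n_sim = 1e5) {
  side <- match.arg(side)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 30) stop("dixon_q: n must be in 3..30", call. = FALSE)
  if (diff(range(values)) == 0) stop("dixon_q: zero range (all values equal)",
                                     call. = FALSE)
  st <- .dixon_stat(values, side)
  # map sorted suspect position back to the input vector
  suspect_value <- sort(values)[st$suspect]
  suspect_index <- which(values == suspect_value)[1]
  null_q <- .dixon_null(n, side, seed, n_sim)
  crit <- if (alpha >= 1) 0 else unname(stats::quantile(null_q, 1 - alpha))
  structure(list(statistic = st$statistic, suspect_index = suspect_index,
                 n = n, critical_value = crit,
                 p_value = mean(null_q >= st$statistic),
                 is_outlier = st$statistic > crit,
                 side = side, alpha = alpha),
            class = "QResult")
}

#' @export
print.QResult <- function(x, ...) {
  cat(sprintf("Dixon Q (%s, n=%d): Q = %.4f, crit(alpha=%g) = %.4f, p = %.4f -> %s\n",
              x$side, x$n, x$statistic, x$alpha, x$critical_value, x$p_value,
              if (x$is_outlier) "OUTLIER" else "no outlier"))
  invisible(x)
}

#' Multi-criteria Dixon outlier scan over samples
#'
#' Scans each QC criterion within each group with Dixon's Q test and
#' returns a `QCReport`.  A sample flagged on any criterion is excluded
#' overall; an array-signal-distribution criterion (several summaries of
#' the same channel) excludes a sample if any one summary flags it.
#' Groups with fewer than 3 samples are skipped with a recorded warning.
#'
#' @param metrics data.frame with columns `sample_id`, `group`,
#'   `criterion`, `value` (one row per sample per criterion).
#' @param alpha significance level per scan (no multiplicity correction:
#'   criteria are applied independently).
#' @param side sidedness of each Dixon scan.
#' @param seed,n_sim Monte-Carlo null parameters.
#' @return a `QCReport`: list with `metrics` (per-row Dixon results),
#'   `exclusions` (sample_id, excluded, reason) and `warnings`.
#' @export
flag_outlier_samples <- function(metrics, alpha = 0.05,
                                 side = "two_sided", seed = 1L, n_sim = 1e5) {
  need <- c("sample_id", "group", "criterion", "value")
  stopifnot(all(need %in% names(metrics)))
  out <- list(); warn <- character()
  for (crit in unique(metrics$criterion)) {
    sub_c <- metrics[metrics$criterion == crit, , drop = FALSE]
    for (g in unique(sub_c$group)) {
      sub <- sub_c[sub_c$group == g, , drop = FALSE]
      if (nrow(sub) < 3) {
        warn <- c(warn, sprintf(
          "criterion '%s' skipped in group '%s': only %d sample(s)",
          crit, g, nrow(sub)))
        next
      }
      if (diff(range(sub$value)) == 0) {
        res <- list(statistic = 0, suspect_index = NA_integer_,
                    critical_value = NA_real_, p_value = 1,
                    is_outlier = FALSE)
      } else {
        res <- dixon_q(sub$value, side = side, alpha = alpha,
                       seed = seed, n_sim = n_sim)
      }
      flagged <- rep(FALSE, nrow(sub))
      if (isTRUE(res$is_outlier)) flagged[res$suspect_index] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sub$sample_id, group = g, criterion = crit,
        value = sub$value, statistic = res$statistic,
        critical_value = res$critical_value, p_value = res$p_value,
        is_outlier = flagged, stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), group = character(),
               criterion = character(), value = numeric(),
               statistic = numeric(), critical_value = numeric(),
               p_value = numeric(), is_outlier = logical())
  samples <- unique(metrics$sample_id)
  reason <- vapply(samples, function(s) {
    paste(unique(rows$criterion[rows$sample_id == s & rows$is_outlier]),
          collapse = ";")
  }, character(1))
  excl <- data.frame(sample_id = samples, excluded = nzchar(reason),
                     reason = reason, stringsAsFactors = FALSE)
  rownames(excl) <- NULL
  structure(list(metrics = rows, exclusions = excl, warnings = warn,
                 alpha = alpha),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d metric scans, %d sample(s) excluded\n",
              nrow(x$metrics), sum(x$exclusions$excluded)))
  if (sum(x$exclusions$excluded))
    print(x$exclusions[x$exclusions$excluded, ])
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Per-sample array signal-distribution QC summaries
#'
#' The five distribution summaries of per-array log2 sample-channel signal
#' used to scan for poor-quality arrays: 25th/50th/75th percentiles,
#' maximum, and median absolute deviation.
#'
#' @param es ExperimentSet (raw or normalized).
#' @param criterion_prefix prefix for the criterion names.
#' @return data.frame in the [flag_outlier_samples()] metrics layout.
#' @export
array_distribution_metrics <- function(es, criterion_prefix = "af3_log2") {
  l2 <- log2(pmax(es$af3, 1))
  summaries <- list(p25 = function(v) stats::quantile(v, 0.25),
                    p50 = function(v) stats::quantile(v, 0.50),
                    p75 = function(v) stats::quantile(v, 0.75),
                    max = function(v) max(v),
                    mad = function(v) stats::mad(v))
  do.call(rbind, lapply(names(summaries), function(nm) {
    data.frame(sample_id = es$samples$sample_id, group = es$samples$group,
               criterion = paste(criterion_prefix, nm, sep = "_"),
               value = apply(l2, 2, summaries[[nm]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Mean fragment size of an electropherogram (50%-area point)
#'
#' Returns the fragment size (nt) at which the cumulative trapezoidal area
#' under the fluorescence trace first reaches 50% of the total area,
#' linearly interpolating the cumulative area between grid points.
#' Invariant to uniform rescaling of the fluorescence.
#'
#' @param trace an `Electropherogram` (list with `size_nt`, `fluorescence`)
#'   or anything coercible: non-decreasing sizes, non-negative fluorescence.
#' @return the 50%-area fragment size in nt.
#' @export
mean_fragment_size <- function(trace) {
  x <- as.numeric(trace$size_nt)
  f <- as.numeric(trace$fluorescence)
  stopifnot(length(x) == length(f), length(x) >= 2,
            all(diff(x) >= 0), all(f >= 0))
  seg <- diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2
  total <- sum(seg)
  if (total <= 0) stop("mean_fragment_size: zero-area trace", call. = FALSE)
  cum <- cumsum(seg)
  half <- total / 2
  i <- which(cum >= half)[1]
  prev <- if (i == 1) 0 else cum[i - 1]
  if (seg[i] == 0) return(x[i])
  x[i] + (half - prev) / seg[i] * (x[i + 1] - x[i])
}
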