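# Population-level descriptive and inferential statistics: control
# normalization, fixed-threshold outlier percentages, exact small-sample
# two-sample KS comparison, CV, and dual-reporter correlations.

#' Normalize intensities to a control sample mean
#'
#' Each experiment is rescaled by the mean fluorescence of a control sample,
#' putting replicate experiments on a common scale.  With the default
#' `reference = 1` the result is in control-mean units; passing a nominal
#' instrument value as `reference` maps the control mean to that value
#' instead (preserving, e.g., an instrument-scale outlier threshold).  The
#' reference and control mean are stored as attributes so the
#' transformation is invertible with [denormalize_events()].
#'
#' @param x numeric intensities, or an `event_table` (all channel columns
#'   are rescaled).
#' @param control_mean mean fluorescence of the control sample (> 0).
#' @param reference value the control mean is mapped to (> 0, default 1).
#' @param channel channel column when `x` is an event table.
#' @return Rescaled object of the same form as `x`.
#' @examples
#' normalize_to_control(c(2, 4), control_mean = 2)  # 1, 2
#' @export
normalize_to_control <- function(x, control_mean, reference = 1,
                                 channel = NULL) {
  stop_scalar_positive(control_mean, "control_mean")
  stop_scalar_positive(reference, "reference")
  f <- reference / control_mean
  if (is.data.frame(x)) {
    ch <- channel %||% event_channels(x)
    for (cc in ch) x[[cc]] <- x[[cc]] * f
  } else {
    x <- x * f
  }
  attr(x, "control_mean") <- control_mean
  attr(x, "reference") <- reference
  x
}

#' @rdname normalize_to_control
#' @export
denormalize_events <- function(x) {
  cm <- attr(x, "control_mean")
  ref <- attr(x, "reference")
  if (is.null(cm) || is.null(ref)) {
    stop("object carries no normalization attributes", call. = FALSE)
  }
  f <- cm / ref
  if (is.data.frame(x)) {
    for (cc in event_channels(x)) x[[cc]] <- x[[cc]] * f
  } else {
    x <- as.numeric(x) * f
  }
  attr(x, "control_mean") <- NULL
  attr(x, "reference") <- NULL
  x
}

#' Percentage of events above a fixed threshold
#'
#' Outliers are defined as events strictly above a fixed threshold of
#' normalized fluorescence (the study convention uses ~1250 A.U. on the
#' instrument scale).  Strict inequality is used for determinism; the
#' distinction is immaterial for continuous data.
#'
#' @param x numeric normalized intensities, or an `event_table`.
#' @param threshold positive threshold (normalized A.U.).
#' @param channel channel column when `x` is an event table.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_outliers(c(100, 1300, 2000, 50), threshold = 1250)  # 50
#' @export
percent_outliers <- function(x, threshold = 1250, channel = NULL) {
  stop_scalar_positive(threshold, "threshold")
  v <- extract_channel(x, channel)
  if (length(v) == 0L) stop("empty event set", call. = FALSE)
  100 * mean(v > threshold)
}

#' Fold change between mean outlier frequencies
#'
#' @param a,b numeric vectors of per-replicate outlier percentages.
#' @return List with `fold` (= `mean(a)/mean(b)`), the group means, SEMs,
#'   a delta-method SEM of the fold, and an `unbounded` flag set when the
#'   denominator mean is zero (fold reported as `Inf`, not an error).
#' @export
fold_outlier_effect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both replicate sets must be non-empty", call. = FALSE)
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  ma <- mean(a); mb <- mean(b)
  if (mb == 0) {
    return(list(fold = Inf, mean_a = ma, mean_b = mb,
                sem_a = sem(a), sem_b = sem(b), sem_fold = NA_real_,
                unbounded = TRUE))
  }
  fold <- ma / mb
  sem_fold <- abs(fold) * sqrt((sem(a) / ma)^2 + (sem(b) / mb)^2)
  list(fold = fold, mean_a = ma, mean_b = mb,
       sem_a = sem(a), sem_b = sem(b), sem_fold = sem_fold,
       unbounded = FALSE)
}

# D for a split of a pooled sample, given the pooled sort order.
ks_D_only <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

#' Two-sample KS test with exact small-sample permutation p-value
#'
#' Treats two small sets of replicate measurements (e.g. per-experiment
#' outlier percentages) as samples from two distributions and tests whether
#' they could come from the same one.  For combined sizes up to `exact_max`
#' the two-sided p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group assignments (the exact permutation null,
#' valid with ties); larger inputs fall back on the asymptotic
#' approximation.  Ties are handled through the pooled ECDF (midrank
#' convention) and flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param exact_max largest combined size for which enumeration is used.
#' @return An object of class `ks_result`: `D`, `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"asymptotic"`), `ties` flag.
#' @examples
#' ks_compare(c(1, 2, 3, 4), c(5, 6, 7, 8))  # D = 1, p = 2/70
#' @export
ks_compare <- function(a, b, exact_max = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each replicate set needs at least 2 values", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  D <- ks_D_only(a, b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (n1 + n2 <= exact_max) {
    pooled <- c(a, b)
    idx <- utils::combn(n1 + n2, n1)
    Dperm <- apply(idx, 2L, function(i) ks_D_only(pooled[i], pooled[-i]))
    p <- mean(Dperm >= D - 1e-12)
    method <- "exact"
  } else {
    p <- suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
    method <- "asymptotic"
  }
  structure(list(D = D, p_value = p, n1 = n1, n2 = n2,
                 method = method, ties = ties),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4g, p = %.4g (%s, n = %d vs %d)%s\n",
              x$D, x$p_value, x$method, x$n1, x$n2,
              if (x$ties) " [ties present]" else ""))
  invisible(x)
}

#' Coefficient of variation
#'
#' Unbiased standard deviation divided by the mean; scale-free, so it is
#' identical on raw and control-normalized fluorescence.
#'
#' @param x numeric intensities (n >= 2, positive mean), or an
#'   `event_table`.
#' @param channel channel column when `x` is an event table.
#' @return CV (dimensionless, >= 0).
#' @export
coefficient_of_variation <- function(x, channel = NULL) {
  v <- extract_channel(x, channel)
  if (length(v) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("CV requires a positive mean", call. = FALSE)
  stats::sd(v) / m
}

#' Pearson and Spearman correlation between two reporter channels
#'
#' @param x,y equal-length numeric vectors (n >= 3) of per-cell intensities
#'   from the two reporters.
#' @return List with `pearson`, `spearman` and `n`.
#' @export
dual_reporter_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("channels differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance channel", call. = FALSE)
  }
  list(pearson = stats::cor(x, y),
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(x))
}

#' Per-replicate noise and outlier statistics for a genotype panel
#'
#' Convenience wrapper producing the tidy per-replicate table emitted by the
#' pipeline: percent outliers (after control normalization) and CV for each
#' population/replicate.
#'
#' @param tables named list of `event_table`s (one per population).
#' @param control_mean mean fluorescence of the control sample (> 0).
#' @param threshold outlier threshold on the reference scale.
#' @param reference value the control mean maps to under normalization.
#' @param channel channel column name.
#' @return A data frame with one row per population x replicate:
#'   `population`, `replicate`, `n`, `percent_outliers`, `cv`.
#' @export
panel_statistics <- function(tables, control_mean, threshold = 1250,
                             reference = 1, channel = NULL) {
  rows <- lapply(names(tables), function(lab) {
    tab <- tables[[lab]]
    ch <- channel %||% attr(tab, "channel") %||% event_channels(tab)[1]
    do.call(rbind, lapply(split(tab, tab$replicate), function(rep_tab) {
      v <- normalize_to_control(as.numeric(rep_tab[[ch[1]]]),
                                control_mean, reference = reference)
      data.frame(population = lab,
                 replicate = rep_tab$replicate[1],
                 n = nrow(rep_tab),
                 percent_outliers = percent_outliers(v, threshold),
                 cv = coefficient_of_variation(v))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
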