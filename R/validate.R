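#' Spearman rank correlation between activation counts and steps
#'
#' Tie-corrected Spearman correlation: both variables are converted to
#' average-assigned ranks and the Pearson correlation of the ranks is
#' returned. The two-sided p-value uses the t-distribution approximation
#' with `n - 2` degrees of freedom (the standard choice at pilot-scale n);
#' a seeded permutation p-value is available for auditing small samples.
#'
#' @param x,y paired numeric vectors (activation counts and step counts);
#'   pairs with a missing value in either are dropped.
#' @param scope label recorded in the result: `"ALL"` for pooled data or a
#'   house identifier.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations when `p_method = "permutation"`.
#' @param perm_seed RNG seed for the permutation null.
#' @param outlier_threshold recorded in the result for provenance (the
#'   filtering itself happens upstream, see [threshold_sweep()]).
#' @return A `validation_result`: list with `scope`, `rho`, `n`, `p_value`,
#'   `p_method`, `outlier_threshold`.
#' @examples
#' spearman_rho(c(0, 1, 2, 3), c(0, 10, 25, 60))$rho  # 1
#' @export
spearman_rho <- function(x, y, scope = "ALL",
                         p_method = c("t", "permutation"),
                         n_perm = 1000L, perm_seed = 1L,
                         outlier_threshold = NA_real_) {
  p_method <- match.arg(p_method)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs, got ", n, call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation undefined: all values tied in one variable",
         call. = FALSE)
  rho <- stats::cor(rx, ry)

  p <- if (p_method == "t") {
    if (abs(rho) >= 1) 0
    else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  } else {
    rho_perm <- withr_seed(perm_seed, {
      vapply(seq_len(n_perm),
             function(i) stats::cor(rx, sample(ry)), numeric(1))
    })
    (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  structure(list(scope = scope, rho = rho, n = n, p_value = p,
                 p_method = p_method,
                 outlier_threshold = outlier_threshold),
            class = "validation_result")
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> scope=%s rho=%.4f n=%d p=%.3g (%s)%s\n",
              x$scope, x$rho, x$n, x$p_value, x$p_method,
              if (is.na(x$outlier_threshold)) ""
              else sprintf(" threshold=%g", x$outlier_threshold)))
  invisible(x)
}

#' Outlier-threshold sensitivity sweep
#'
#' Recomputes the Spearman correlation after excluding pairs whose step
#' count strictly exceeds each candidate threshold, by default 100 to 400
#' steps in increments of 50 — the procedure used to justify the 100-step
#' outlier cutoff. Retained n is non-decreasing in the threshold.
#'
#' @param x,y paired activation counts and step counts.
#' @param thresholds numeric vector of step thresholds (default
#'   `seq(100, 400, by = 50)`).
#' @return A `data.table` ordered by threshold with columns `threshold`,
#'   `rho`, `n`, `p_value`.
#' @export
threshold_sweep <- function(x, y, thresholds = seq(100, 400, by = 50)) {
  if (!length(thresholds)) stop("threshold list is empty", call. = FALSE)
  if (all(is.na(y))) stop("step data required for the sweep", call. = FALSE)
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(thr) {
    keep <- !is.na(x) & !is.na(y) & y <= thr
    r <- spearman_rho(x[keep], y[keep], outlier_threshold = thr)
    data.table::data.table(threshold = thr, rho = r$rho, n = r$n,
                           p_value = r$p_value)
  })
  data.table::rbindlist(rows)
}

#' Full step-count validation report
#'
#' The pilot-study statistics in one object: the pooled Spearman correlation
#' between per-interval activation counts and steps, the per-house
#' correlations and their min–max range, the pooled correlation recomputed
#' without noise removal (the filter's effect made visible), and the
#' outlier-threshold sensitivity sweep. Pairs are taken from intervals with
#' step data; intervals excluded as noise or step outliers under `config`
#' are dropped from the primary estimates.
#'
#' @param records interval table with `steps` joined (see [join_steps()]).
#' @param config a [classifier_config()].
#' @return A list with elements `pooled`, `per_house` (a `data.table`),
#'   `rho_range`, `pooled_unfiltered`, and `sweep`.
#' @export
validation_report <- function(records, config = classifier_config()) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("house_id", "timestamp", "activation_count", "steps")
                %in% names(dt)))
  paired <- dt[!is.na(steps) & !is.na(activation_count)]
  if (nrow(paired) < 3L)
    stop("too few intervals with step data for validation", call. = FALSE)

  filt <- filter_noise(paired, config)
  filt <- filter_step_outliers(filt, config)
  clean <- filt[is.na(label) | label != "EXCLUDED"]

  pooled <- spearman_rho(clean$activation_count, clean$steps,
                         outlier_threshold = config$outlier_step_threshold)
  per_house <- clean[, {
    r <- spearman_rho(activation_count, steps, scope = .BY$house_id)
    list(rho = r$rho, n = r$n, p_value = r$p_value)
  }, by = house_id]
  pooled_unfiltered <- spearman_rho(paired$activation_count, paired$steps)
  sweep <- threshold_sweep(paired$activation_count, paired$steps)

  list(pooled = pooled,
       per_house = per_house,
       rho_range = range(per_house$rho),
       pooled_unfiltered = pooled_unfiltered,
       sweep = sweep)
}
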