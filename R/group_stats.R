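#' Friedman test across array conditions
#'
#' Rank-based Friedman test (chi-square reference) of a complete
#' sessions x conditions performance table. The degenerate all-tied table
#' (every session identical across conditions) has statistic 0 and p = 1.
#'
#' @param perf Numeric matrix or data frame, rows = sessions, columns =
#'   conditions; no missing cells.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
friedman_conditions <- function(perf) {
  perf <- as.matrix(perf)
  if (nrow(perf) < 3L) stop("need >= 3 sessions", call. = FALSE)
  if (any(!is.finite(perf))) stop("missing cells in performance table", call. = FALSE)
  if (all(apply(perf, 1L, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, p_value = 1, df = ncol(perf) - 1L))
  ft <- stats::friedman.test(perf)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter))
}

#' Pairwise Wilcoxon signed-rank comparisons between conditions
#'
#' Two-sided signed-rank test for every pair of conditions over sessions,
#' with zero differences dropped; exact p-values for up to 25 non-zero
#' differences (normal approximation with continuity correction beyond, or
#' when ties prevent exactness). Significance is judged at the Bonferroni
#' threshold `alpha_family / n_pairs` (0.05 / 3 = 0.0167 for the three
#' array-condition pairs).
#'
#' @inheritParams friedman_conditions
#' @param alpha_family Family-wise alpha for the pairwise family.
#' @return Data frame: `pair`, `statistic` (V), `p_value`, `significant`,
#'   `degenerate`, `threshold`.
#' @export
wilcoxon_pairwise <- function(perf, alpha_family = 0.05) {
  perf <- as.matrix(perf)
  cn <- colnames(perf)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(perf)))
  pairs <- utils::combn(seq_len(ncol(perf)), 2L)
  thr <- bonferroni_alpha(alpha_family, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- perf[, a] - perf[, b]
    d <- d[d != 0]
    if (length(d) == 0L) {
      return(data.frame(pair = paste(cn[a], cn[b], sep = "-"),
                        statistic = NA_real_, p_value = NA_real_,
                        significant = FALSE, degenerate = TRUE,
                        threshold = thr))
    }
    wt <- suppressWarnings(stats::wilcox.test(d, exact = length(d) <= 25,
                                              correct = TRUE))
    data.frame(pair = paste(cn[a], cn[b], sep = "-"),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               significant = wt$p.value < thr, degenerate = FALSE,
               threshold = thr)
  })
  do.call(rbind, rows)
}

#' Compare decoding performance across array conditions
#'
#' Friedman test (alpha 0.05) over the sessions x conditions table; only
#' when it is significant are post-hoc pairwise Wilcoxon signed-rank tests
#' run (Bonferroni-corrected threshold 0.05/3).
#'
#' @inheritParams friedman_conditions
#' @param metric Label of the compared metric (for printing).
#' @param alpha Friedman significance level gating the post-hoc tests.
#' @return A `"condition_comparison"`: list with `metric`,
#'   `friedman` (statistic, p), and `pairwise` (data frame, or `NULL` when
#'   the Friedman gate fails).
#' @export
compare_conditions <- function(perf, metric = "r2", alpha = 0.05) {
  fr <- friedman_conditions(perf)
  pw <- if (fr$p_value < alpha) wilcoxon_pairwise(perf) else NULL
  structure(list(metric = metric, friedman = fr, pairwise = pw,
                 n_sessions = nrow(as.matrix(perf))),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s, %d sessions): Friedman chi2 = %.3f, p = %.4g\n",
              x$metric, x$n_sessions, x$friedman$statistic, x$friedman$p_value))
  if (is.null(x$pairwise)) {
    cat("  Friedman not significant; post-hoc comparisons not performed\n")
  } else {
    for (i in seq_len(nrow(x$pairwise))) {
      r <- x$pairwise[i, ]
      cat(sprintf("  %-16s V = %5.1f  p = %.4g %s\n", r$pair, r$statistic,
                  r$p_value, if (isTRUE(r$significant)) "*" else ""))
    }
  }
  invisible(x)
}
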