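#' Fixed gating cutoffs for an experiment
#'
#' One `gate_config` is applied identically to every nucleus of an
#' experiment: cells are GFP-positive when their GFP/RFP ratio strictly
#' exceeds `gfp_ratio_cutoff`, and marker-positive (EdU, phospho-H3) when
#' their integrated nuclear marker signal strictly exceeds `marker_cutoff`.
#' Ties fall on the negative side.
#'
#' @param gfp_ratio_cutoff Dimensionless GFP/RFP ratio cutoff (> 0).
#' @param marker_cutoff Integrated-marker cutoff, intensity x pixels (> 0).
#' @param provenance How the cutoffs were chosen: `"manual"`,
#'   `"auto_log_valley"` or `"auto_otsu"` (bookkeeping only).
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(gfp_ratio_cutoff, marker_cutoff,
                        provenance = c("manual", "auto_log_valley",
                                       "auto_otsu")) {
  provenance <- match.arg(provenance)
  stopifnot(
    "gfp_ratio_cutoff must be > 0" = gfp_ratio_cutoff > 0,
    "marker_cutoff must be > 0" = marker_cutoff > 0
  )
  structure(list(gfp_ratio_cutoff = gfp_ratio_cutoff,
                 marker_cutoff = marker_cutoff,
                 provenance = provenance),
            class = "gate_config")
}

#' Gate nuclei into GFP+/- and marker+/- classes
#'
#' Adds logical columns `is_gfp_pos` (`ratio > gfp_ratio_cutoff`) and
#' `is_marker_pos` (`integrated_marker > marker_cutoff`) using the strictly
#' greater convention; the same cutoffs are applied to every record.
#'
#' @param records Data frame with `ratio` and `integrated_marker` columns
#'   (from [measure_nuclei()]).
#' @param gate A [gate_config()].
#' @return `records` with the two gate flags appended.
#' @export
gate_cells <- function(records, gate) {
  stopifnot(inherits(gate, "gate_config"))
  for (col in c("ratio", "integrated_marker")) {
    if (is.null(records[[col]]) || anyNA(records[[col]])) {
      stop("records are missing measured field '", col, "'")
    }
  }
  records$is_gfp_pos <- records$ratio > gate$gfp_ratio_cutoff
  records$is_marker_pos <- records$integrated_marker > gate$marker_cutoff
  records
}

#' Suggest a gating cutoff from a bimodal intensity distribution
#'
#' Works on log10-transformed values, where fluorescence positive/negative
#' mixtures are near-symmetric: either finds the valley of a kernel-smoothed
#' density between its two dominant modes (`"auto_log_valley"`) or applies
#' Otsu's threshold to the log-intensity histogram (`"auto_otsu"`), then
#' back-transforms. Deterministic given the value list.
#'
#' @param values Positive numeric values (>= 2 distinct).
#' @param method `"auto_log_valley"` (default) or `"auto_otsu"`.
#' @return The suggested cutoff on the original (linear) scale.
#' @export
#' @examples
#' suggest_cutoff(c(rlnorm(300, log(0.1), 0.3), rlnorm(300, log(10), 0.3)))
suggest_cutoff <- function(values,
                           method = c("auto_log_valley", "auto_otsu")) {
  method <- match.arg(method)
  if (any(values <= 0)) stop("values must be positive")
  if (length(unique(values)) < 2) {
    stop("degenerate input (fewer than 2 distinct values); ",
         "choose a manual cutoff")
  }
  lv <- log10(values)
  if (method == "auto_otsu") {
    v01 <- (lv - min(lv)) / (max(lv) - min(lv))
    thr <- EBImage::otsu(EBImage::Image(matrix(v01, nrow = 1)),
                         range = c(0, 1), levels = 256)
    return(10^(min(lv) + thr * (max(lv) - min(lv))))
  }
  d <- stats::density(lv)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) {
    stop("distribution looks unimodal on the log scale; ",
         "choose a manual cutoff")
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1
  10^d$x[valley]
}

#' Per-well counts and fractions by GFP and marker status
#'
#' Groups gated records by (well, timepoint, condition) and reports the
#' counts and percentages of the lineage analysis: total cells, GFP+ cells,
#' and marker+ cells within the GFP+ and GFP- subpopulations. A fraction
#' whose denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param records Gated records (see [gate_cells()]).
#' @return Data frame with one row per (well, timepoint, condition):
#'   counts `n_total`, `n_gfp_pos`, `n_gfp_neg`, `n_marker_pos_in_gfp_pos`,
#'   `n_marker_pos_in_gfp_neg` and percentages `pct_gfp_pos`,
#'   `pct_marker_in_gfp_pos`, `pct_marker_in_gfp_neg`.
#' @export
summarize_wells <- function(records) {
  if (is.null(records$is_gfp_pos) || is.null(records$is_marker_pos)) {
    stop("records must be gated first (see gate_cells)")
  }
  if (nrow(records) == 0) {
    return(data.frame(
      well = character(0), timepoint = numeric(0), condition = character(0),
      n_total = integer(0), n_gfp_pos = integer(0), n_gfp_neg = integer(0),
      n_marker_pos_in_gfp_pos = integer(0),
      n_marker_pos_in_gfp_neg = integer(0),
      pct_gfp_pos = numeric(0), pct_marker_in_gfp_pos = numeric(0),
      pct_marker_in_gfp_neg = numeric(0)
    ))
  }
  key <- interaction(records$well, records$timepoint, records$condition,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n_total <- nrow(g)
    n_gfp_pos <- sum(g$is_gfp_pos)
    n_gfp_neg <- n_total - n_gfp_pos
    n_mk_pos_gp <- sum(g$is_marker_pos & g$is_gfp_pos)
    n_mk_pos_gn <- sum(g$is_marker_pos & !g$is_gfp_pos)
    pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    data.frame(
      well = g$well[1], timepoint = g$timepoint[1], condition = g$condition[1],
      n_total = n_total, n_gfp_pos = n_gfp_pos, n_gfp_neg = n_gfp_neg,
      n_marker_pos_in_gfp_pos = n_mk_pos_gp,
      n_marker_pos_in_gfp_neg = n_mk_pos_gn,
      pct_gfp_pos = pct(n_gfp_pos, n_total),
      pct_marker_in_gfp_pos = pct(n_mk_pos_gp, n_gfp_pos),
      pct_marker_in_gfp_neg = pct(n_mk_pos_gn, n_gfp_neg)
    )
  }))
  rownames(out) <- NULL
  out[order(out$timepoint, out$condition, out$well), , drop = FALSE]
}

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n); for a single value the SEM is undefined and reported as `NA`.
#'
#' @param values Numeric vector (length >= 1).
#' @return Named numeric vector `c(mean =, sem =, n =)`.
#' @export
#' @examples
#' mean_sem(c(1, 2, 3))  # mean 2, sem 1/sqrt(3)
mean_sem <- function(values) {
  if (length(values) == 0) stop("mean_sem needs at least one value")
  n <- length(values)
  sem <- if (n < 2) NA_real_ else stats::sd(values) / sqrt(n)
  c(mean = mean(values), sem = sem, n = n)
}

#' Two-sample Student t test on replicate values
#'
#' Pooled-variance two-tailed Student t test by default (degrees of freedom
#' `nA + nB - 2`); Welch's unequal-variance variant via
#' `var_equal = FALSE`. Degenerate inputs are handled explicitly: two groups
#' with zero pooled variance and equal means give `t = 0, p = 1`; zero
#' variance with unequal means gives infinite `t`, `p = 0` and a note.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2 (biological
#'   replicates, e.g. wells or mice — never individual cells).
#' @param var_equal Pooled variance (TRUE, default) or Welch (FALSE).
#' @return One-row data frame: `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `t_statistic`, `df`, `p_value`, `note`.
#' @export
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
two_sample_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 replicates")
  }
  na <- length(group_a); nb <- length(group_b)
  base <- data.frame(n_a = na, n_b = nb,
                     mean_a = mean(group_a), mean_b = mean(group_b))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(cbind(base, data.frame(t_statistic = 0, df = na + nb - 2,
                                    p_value = 1, note = "zero variance")))
    }
    t_inf <- sign(mean(group_a) - mean(group_b)) * Inf
    return(cbind(base, data.frame(t_statistic = t_inf, df = na + nb - 2,
                                  p_value = 0,
                                  note = "zero variance, unequal means")))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  cbind(base, data.frame(t_statistic = unname(ht$statistic),
                         df = unname(ht$parameter),
                         p_value = ht$p.value, note = ""))
}

#' Time-course table of marker-positive fractions
#'
#' Reshapes well summaries into a long table with one row per (timepoint,
#' condition, population), where population is `gfp_pos` or `gfp_neg`, giving
#' the number of replicate wells with a defined fraction and the mean and SEM
#' of the per-well marker-positive percentages. Rows are sorted by timepoint.
#' (timepoint, condition) combinations with no wells are simply absent.
#'
#' @param summaries Data frame from [summarize_wells()].
#' @return Long data frame: `timepoint`, `condition`, `population`,
#'   `n_wells`, `mean_pct_marker_pos`, `sem_pct_marker_pos`.
#' @export
timecourse_table <- function(summaries) {
  if (nrow(summaries) == 0) {
    return(data.frame(timepoint = numeric(0), condition = character(0),
                      population = character(0), n_wells = integer(0),
                      mean_pct_marker_pos = numeric(0),
                      sem_pct_marker_pos = numeric(0)))
  }
  key <- interaction(summaries$timepoint, summaries$condition,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(summaries, key), function(g) {
    one <- function(pop, vals) {
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) return(NULL)
      ms <- mean_sem(vals)
      data.frame(timepoint = g$timepoint[1], condition = g$condition[1],
                 population = pop, n_wells = length(vals),
                 mean_pct_marker_pos = ms[["mean"]],
                 sem_pct_marker_pos = ms[["sem"]])
    }
    rbind(one("gfp_pos", g$pct_marker_in_gfp_pos),
          one("gfp_neg", g$pct_marker_in_gfp_neg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$timepoint, out$condition, out$population), , drop = FALSE]
}
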