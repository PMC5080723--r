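#' Empirical detection floor from null genes
#'
#' The lower detection threshold is the maximum log2 expression observed
#' for a set of genes known to be unexpressed (Y-chromosome genes in a
#' female cell line; the generator's null genes in simulation).
#'
#' @param expression An `expression_matrix`.
#' @param null_gene_ids Nonempty character vector of null gene ids.
#' @return Log2 detection floor (scalar).
#' @export
detection_floor <- function(expression, null_gene_ids) {
  if (length(null_gene_ids) == 0L) stop("null gene set is empty")
  rows <- rownames(expression$values) %in% null_gene_ids
  if (!any(rows)) stop("no null gene found in the expression matrix")
  max(expression$values[rows, , drop = FALSE])
}

#' Detected / expressed flags per gene
#'
#' A gene is detected when its per-time-point mean exceeds the detection
#' floor in at least one time point, and expressed well above background
#' when that mean exceeds `expressed_threshold_units` (non-log2; 100 units
#' = 6.64 in log2) in at least one time point.
#'
#' @param expression An `expression_matrix`.
#' @param params A [pipeline_params()].
#' @param floor Log2 detection floor (e.g. from [detection_floor()]).
#' @return Data frame: gene_id, detected, expressed.
#' @export
expressed_flags <- function(expression, params = pipeline_params(),
                            floor = -Inf) {
  tm <- timepoint_means(expression)
  thresh <- log2(params$expressed_threshold_units)
  data.frame(
    gene_id = rownames(tm),
    detected = apply(tm > floor, 1, any),
    expressed = apply(tm > thresh, 1, any),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Median expression by gene group with pairwise rank tests
#'
#' Per-group median of per-gene mean expression at one time point, with
#' two-sided unpaired rank-sum tests between every pair of groups. Groups
#' with fewer than 3 genes are reported but excluded from testing.
#'
#' @param expression An `expression_matrix`.
#' @param gene_groups Named list of disjoint gene-id vectors.
#' @param timepoint Time-point label.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return List: `medians` (data frame group, n, median), `tests` (data
#'   frame group1, group2, p_value, significant).
#' @export
median_by_group <- function(expression, gene_groups, timepoint,
                            alpha = 0.05) {
  tm <- timepoint_means(expression)
  stopifnot(timepoint %in% colnames(tm))
  vals <- lapply(gene_groups, function(ids) {
    tm[rownames(tm) %in% ids, timepoint]
  })
  medians <- data.frame(
    group = names(vals),
    n = lengths(vals),
    median = vapply(vals, function(v) stats::median(v), numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  testable <- names(vals)[lengths(vals) >= 3L]
  skipped <- setdiff(names(vals), testable)
  if (length(skipped)) {
    warning("group(s) with < 3 genes skipped from testing: ",
            paste(skipped, collapse = ", "))
  }
  tests <- NULL
  if (length(testable) >= 2L) {
    pairs <- utils::combn(testable, 2)
    tests <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      p_value = apply(pairs, 2, function(pr) {
        stats::wilcox.test(vals[[pr[1]]], vals[[pr[2]]], exact = FALSE)$p.value
      }),
      stringsAsFactors = FALSE
    )
    tests$significant <- tests$p_value < alpha
  }
  list(medians = medians, tests = tests)
}

# One-way fixed-effects ANOVA p-value for one gene's values across time
# points; degenerate data (no variance anywhere) carries no evidence -> 1.
anova_p <- function(values, groups) {
  if (stats::var(values) == 0) return(1)
  res <- tryCatch(
    stats::oneway.test(values ~ groups, var.equal = TRUE),
    error = function(e) NULL
  )
  if (is.null(res) || is.na(res$p.value)) 1 else res$p.value
}

#' Differential-expression calls from the two one-way ANOVA models
#'
#' Model `hypoxia` tests changes across t0/t8/t24; model `reoxygenation`
#' across t24/reox8/t0 (normoxia as putative endpoint). Per gene, a classic
#' fixed-effects one-way ANOVA F-test across the model's time points;
#' p-values are corrected by Benjamini-Hochberg FDR over expressed genes.
#' A gene is significant when it is expressed, its largest absolute log2
#' fold change between any two of the model's time points is at least
#' `fc_log2_min`, and its q-value is at most `qvalue_max`.
#'
#' @param expression An `expression_matrix`.
#' @param params A [pipeline_params()].
#' @param models Named list of time-point subsets (defaults to the two
#'   study models).
#' @return Data frame: gene_id, model, p_value, q_value, max_abs_log2_fc,
#'   expressed, significant.
#' @export
differential_calls <- function(expression, params = pipeline_params(),
                               models = list(
                                 hypoxia = c("t0", "t8", "t24"),
                                 reoxygenation = c("t24", "reox8", "t0")
                               )) {
  flags <- expressed_flags(expression, params)
  out <- lapply(names(models), function(mname) {
    tps <- models[[mname]]
    stopifnot(all(tps %in% expression$timepoints))
    cols <- expression$timepoints %in% tps
    vals <- expression$values[, cols, drop = FALSE]
    groups <- factor(expression$timepoints[cols], levels = tps)
    p <- apply(vals, 1, anova_p, groups = groups)
    tm <- timepoint_means(expression)[, tps, drop = FALSE]
    fc <- apply(tm, 1, function(m) max(stats::dist(m)))
    expressed <- flags$expressed[match(rownames(vals), flags$gene_id)]
    q <- rep(NA_real_, length(p))
    q[expressed] <- stats::p.adjust(p[expressed], method = "BH")
    data.frame(
      gene_id = rownames(vals),
      model = mname,
      p_value = p,
      q_value = q,
      max_abs_log2_fc = fc,
      expressed = expressed,
      significant = expressed & fc >= params$fc_log2_min &
        !is.na(q) & q <= params$qvalue_max,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
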