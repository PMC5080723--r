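#' Per-gene mark states from the two mark calls
#'
#' Pure function of the H3K4me3 and H3K27me3 calls at one time point:
#' bivalent when both marks are present, `K4only`/`K27only` for a single
#' mark, `none` otherwise.
#'
#' @param k4_calls,k27_calls Data frames from [call_gene_marks()] covering
#'   the same gene universe and time point.
#' @return Data frame: gene_id, timepoint, state (factor over
#'   `MARK_STATES`).
#' @export
mark_states <- function(k4_calls, k27_calls) {
  if (!setequal(k4_calls$gene_id, k27_calls$gene_id)) {
    stop("mark calls cover different gene universes")
  }
  tp <- unique(c(k4_calls$timepoint, k27_calls$timepoint))
  if (length(tp) != 1L) stop("mark calls are from different time points")
  k27 <- k27_calls$marked[match(k4_calls$gene_id, k27_calls$gene_id)]
  k4 <- k4_calls$marked
  state <- ifelse(k4 & k27, "bivalent",
                  ifelse(k4, "K4only", ifelse(k27, "K27only", "none")))
  data.frame(gene_id = k4_calls$gene_id, timepoint = tp,
             state = factor(state, levels = MARK_STATES),
             stringsAsFactors = FALSE)
}

#' State-transition table between two time points
#'
#' Full 4x4 count matrix over `MARK_STATES` plus per-cell gene lists and
#' the derived bivalency-gain summaries: gain of H3K4me3 (K27only ->
#' bivalent), gain of H3K27me3 (K4only -> bivalent), gain of both (none ->
#' bivalent) and preexisting bivalency (bivalent -> bivalent).
#'
#' @param states_a,states_b Data frames from [mark_states()] over the same
#'   gene universe.
#' @return List of class `transition_table`: `from`, `to`, `counts`,
#'   `gene_lists`, `summaries`.
#' @export
transitions <- function(states_a, states_b) {
  if (!setequal(states_a$gene_id, states_b$gene_id)) {
    stop("state vectors cover different gene universes")
  }
  b <- states_b$state[match(states_a$gene_id, states_b$gene_id)]
  a <- states_a$state
  counts <- table(from = a, to = b)
  gene_lists <- lapply(stats::setNames(MARK_STATES, MARK_STATES),
                       function(fs) {
    lapply(stats::setNames(MARK_STATES, MARK_STATES), function(ts) {
      states_a$gene_id[a == fs & b == ts]
    })
  })
  structure(
    list(from = unique(states_a$timepoint), to = unique(states_b$timepoint),
         counts = unclass(counts), gene_lists = gene_lists,
         summaries = c(
           bivalent_by_gain_of_K4 = counts["K27only", "bivalent"],
           bivalent_by_gain_of_K27 = counts["K4only", "bivalent"],
           bivalent_by_gain_of_both = counts["none", "bivalent"],
           bivalent_preexisting = counts["bivalent", "bivalent"]
         )),
    class = "transition_table"
  )
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %s -> %s\n", x$from, x$to))
  print(x$counts)
  invisible(x)
}

#' Bivalency trajectory classes over the full time course
#'
#' Labels each gene from its ordered states (t0, t8, t24, reox8):
#' `preexisting-retained` (bivalent at t0 and still at reox8),
#' `gained-retained` (not bivalent at t0, bivalent by t8 or t24, still
#' bivalent at reox8), `gained-lost` (gained but not bivalent at reox8),
#' `never` (bivalent at no time point), `other` (remaining patterns, e.g.
#' preexisting bivalency lost).
#'
#' @param states_by_tp Named list of [mark_states()] data frames, one per
#'   time point in `TIMEPOINTS` order.
#' @return List: `labels` (data frame gene_id, label), `counts`,
#'   `retained_fraction_of_gained` (gained-retained over all gained).
#' @export
retention <- function(states_by_tp) {
  stopifnot(all(TIMEPOINTS %in% names(states_by_tp)))
  ids <- states_by_tp[[TIMEPOINTS[1]]]$gene_id
  biv <- sapply(TIMEPOINTS, function(tp) {
    s <- states_by_tp[[tp]]
    (s$state == "bivalent")[match(ids, s$gene_id)]
  })
  gained <- !biv[, "t0"] & (biv[, "t8"] | biv[, "t24"])
  label <- rep("other", length(ids))
  label[rowSums(biv) == 0L] <- "never"
  label[biv[, "t0"] & biv[, "reox8"]] <- "preexisting-retained"
  label[gained & biv[, "reox8"]] <- "gained-retained"
  label[gained & !biv[, "reox8"]] <- "gained-lost"
  n_gained <- sum(gained)
  list(
    labels = data.frame(gene_id = ids, label = label,
                        stringsAsFactors = FALSE),
    counts = table(factor(label, levels = c("never", "preexisting-retained",
                                            "gained-retained", "gained-lost",
                                            "other"))),
    retained_fraction_of_gained =
      if (n_gained > 0) sum(gained & biv[, "reox8"]) / n_gained else NaN
  )
}

#' Overlap of a query gene set with a reference set
#'
#' Percentage of the query found in the reference (the default), or the
#' symmetric Jaccard percentage.
#'
#' @param query_gene_ids,reference_gene_ids Character vectors (nonempty).
#' @param method "query" (100 * |q n r| / |q|) or "jaccard"
#'   (100 * |q n r| / |q u r|).
#' @return Percentage (0-100).
#' @export
reference_overlap <- function(query_gene_ids, reference_gene_ids,
                              method = c("query", "jaccard")) {
  method <- match.arg(method)
  q <- unique(query_gene_ids)
  r <- unique(reference_gene_ids)
  if (length(q) == 0L) stop("query gene set is empty")
  if (length(r) == 0L) stop("reference gene set is empty")
  inter <- length(intersect(q, r))
  denom <- if (method == "query") length(q) else length(union(q, r))
  100 * inter / denom
}
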