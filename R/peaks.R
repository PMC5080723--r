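#' Construct a peak set
#'
#' A peak set is one ChIP-seq sample's enriched intervals for one mark at one
#' time point: a data frame with columns `chrom`, `start`, `end` (0-based
#' half-open), `height` (summit intensity) and `area` (cumulative enrichment
#' under the peak), sorted by position, carrying the mark, time point and the
#' multiplicative scale factor applied so far (1 before normalization).
#'
#' @param peaks Data frame with columns chrom, start, end, height, area.
#' @param mark One of `MARKS`.
#' @param timepoint One of `TIMEPOINTS`.
#' @param scale_factor Positive multiplier already applied to heights/areas.
#' @return A `peak_set` object.
#' @export
peak_set <- function(peaks, mark, timepoint, scale_factor = 1) {
  mark <- match.arg(mark, MARKS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  required <- c("chrom", "start", "end", "height", "area")
  if (!all(required %in% names(peaks))) {
    stop("peak table must have columns: ", paste(required, collapse = ", "))
  }
  peaks <- peaks[required]
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  validate_peaks(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(peaks = peaks, mark = mark, timepoint = timepoint,
         scale_factor = scale_factor),
    class = "peak_set"
  )
}

validate_peaks <- function(peaks) {
  if (nrow(peaks) == 0L) return(invisible(TRUE))
  bad <- which(!(peaks$start >= 0L & peaks$start < peaks$end))
  if (length(bad)) {
    stop("invalid peak interval (need 0 <= start < end) at row ", bad[1])
  }
  if (any(peaks$height < 0) || any(peaks$area < 0)) {
    stop("peak height and area must be nonnegative")
  }
  len <- peaks$end - peaks$start
  over <- which(peaks$area > peaks$height * len + 1e-9)
  if (length(over)) {
    stop("peak area exceeds height * length at row ", over[1])
  }
  invisible(TRUE)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s @ %s: %d peaks, scale_factor %.4g\n",
              x$mark, x$timepoint, nrow(x$peaks), x$scale_factor))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param ps A `peak_set`.
#' @export
n_peaks <- function(ps) nrow(ps$peaks)

#' Read a peak file
#'
#' Peak files are tab-separated BED5+ (`chrom start end height area`),
#' 0-based half-open; lines starting with `#` are comments. Malformed rows
#' raise an error naming the line.
#'
#' @inheritParams peak_set
#' @param path File path.
#' @return A `peak_set`, sorted by position.
#' @export
read_peaks <- function(path, mark, timepoint) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), height = numeric(),
                        area = numeric())
    return(peak_set(empty, mark, timepoint))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop(sprintf("malformed peak line %d in %s: expected 5 tab-separated fields",
                 line_no[which(nf < 5L)[1]], path))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  height <- suppressWarnings(as.numeric(m[, 4]))
  area <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(height) | is.na(area))
  if (length(bad)) {
    stop(sprintf("malformed peak line %d in %s: non-numeric field",
                 line_no[bad[1]], path))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d in %s: end <= start",
                 line_no[bad[1]], path))
  }
  peak_set(data.frame(chrom = m[, 1], start = start, end = end,
                      height = height, area = area,
                      stringsAsFactors = FALSE),
           mark, timepoint)
}

#' Write a peak set as BED5+
#'
#' Inverse of [read_peaks()]: tab-separated chrom, start, end, height, area.
#'
#' @param ps A `peak_set`.
#' @param path Output path.
#' @export
write_peaks <- function(ps, path) {
  df <- ps$peaks
  lines <- sprintf("%s\t%d\t%d\t%.10g\t%.10g",
                   df$chrom, df$start, df$end, df$height, df$area)
  writeLines(lines, path)
  invisible(path)
}

#' Rescale a peak set
#'
#' Multiplies all heights and areas by `factor` and accumulates it into the
#' set's scale factor.
#'
#' @param ps A `peak_set`.
#' @param factor Positive multiplier.
#' @export
scale_peak_set <- function(ps, factor) {
  stopifnot(factor > 0)
  ps$peaks$height <- ps$peaks$height * factor
  ps$peaks$area <- ps$peaks$area * factor
  ps$scale_factor <- ps$scale_factor * factor
  ps
}

#' Drop peaks at or below a height cutoff
#'
#' @param ps A `peak_set` (scaled units).
#' @param cutoff Background height cutoff; peaks must be strictly above it.
#' @export
filter_background <- function(ps, cutoff) {
  ps$peaks <- ps$peaks[ps$peaks$height > cutoff, , drop = FALSE]
  rownames(ps$peaks) <- NULL
  ps
}
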