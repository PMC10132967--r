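#' Genomic interval tables
#'
#' Intervals throughout the package are plain data frames with columns
#' `chrom` (character), `start` and `end` (integer-valued, 1-based inclusive)
#' and optionally `strand`. Interval arithmetic (merging, intersection,
#' overlap detection) is delegated to GenomicRanges/IRanges; these helpers
#' convert between the two representations at the module boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @param strand Optional strand (`"+"`, `"-"` or `"*"`).
#' @return A validated interval data frame.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  df
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

as_granges <- function(df) {
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

granges_to_df <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = as.numeric(GenomicRanges::start(gr)),
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Merge intervals separated by at most a gap
#'
#' @param df Interval data frame.
#' @param max_gap Maximum gap in bp between intervals that are merged
#'   (0 merges only overlapping/abutting intervals).
#' @return Sorted, non-overlapping interval data frame.
#' @export
merge_intervals <- function(df, max_gap = 0) {
  gr <- as_granges(df)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                              min.gapwidth = max_gap + 1)
  granges_to_df(gr)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Total length in bp of an interval set
#' @param df Interval data frame (1-based inclusive coordinates).
#' @export
intervals_total_length <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start + 1)
}

# Base-R interval scans for the query helpers below: these run in the
# similarity null loop and the per-amplicon classifier, where building a
# GRanges per call dominates runtime. Interval sets here are tiny (a
# handful of rows), so a sort-and-scan is both exact and fast; equivalence
# with the GenomicRanges route is asserted by a property test.
iv_merge_base <- function(df, max_gap = 0) {
  n <- nrow(df)
  if (n <= 1) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  keep_s <- numeric(0); keep_e <- numeric(0); keep_c <- character(0)
  cs <- df$chrom[1]; s <- df$start[1]; e <- df$end[1]
  for (i in 2:n) {
    if (df$chrom[i] == cs && df$start[i] <= e + max_gap + 1) {
      e <- max(e, df$end[i])
    } else {
      keep_c <- c(keep_c, cs); keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
      cs <- df$chrom[i]; s <- df$start[i]; e <- df$end[i]
    }
  }
  data.frame(chrom = c(keep_c, cs), start = c(keep_s, s), end = c(keep_e, e),
             stringsAsFactors = FALSE)
}

intervals_intersect_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  a <- iv_merge_base(a[, c("chrom", "start", "end")])
  b <- iv_merge_base(b[, c("chrom", "start", "end")])
  total <- 0
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == chr, ]; bi <- b[b$chrom == chr, ]
    ov <- pmin(rep(ai$end, each = nrow(bi)), bi$end) -
      pmax(rep(ai$start, each = nrow(bi)), bi$start) + 1
    total <- total + sum(ov[ov > 0])
  }
  total
}

intervals_union_length <- function(a, b) {
  intervals_total_length(
    iv_merge_base(rbind(a[, c("chrom", "start", "end")],
                        b[, c("chrom", "start", "end")])))
}

intervals_overlap_any <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  intervals_intersect_length(a, b) > 0
}

# membership of points in an interval set, with slop bp of tolerance
point_in_intervals <- function(chrom, pos, df, slop = 0) {
  vapply(seq_along(pos), function(i) {
    any(df$chrom == chrom[i] & df$start - slop <= pos[i] &
          df$end + slop >= pos[i])
  }, logical(1))
}

#' Write intervals as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention at the writer boundary.
#'
#' @param df Interval data frame; an optional `name` column becomes BED
#'   column 4.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  df <- sort_intervals(df)
  out <- data.frame(chrom = df$chrom,
                    start = format_int(df$start - 1),
                    end = format_int(df$end),
                    stringsAsFactors = FALSE)
  if (!is.null(df$name)) out$name <- df$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fixed-format numeric rendering so emitted files are byte-stable
format_int <- function(x) sprintf("%d", as.integer(round(x)))
format_cn <- function(x) sprintf("%.6f", x)
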