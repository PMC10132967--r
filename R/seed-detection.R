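#' Focal-amplification seed detection
#'
#' Copy-number segments are filtered into candidate focal-amplification seed
#' regions: segments above a copy-number threshold are kept, nearby kept
#' segments are merged, and merged intervals below a size threshold are
#' dropped. Thresholds are cohort-specific and exclusive ("greater than"):
#' a segment exactly at the threshold is dropped.
#'
#' @name seed-detection
NULL

#' Seed-calling parameters
#'
#' @param cn_min Copy-number threshold, exclusive (segments must exceed it).
#' @param size_min Size threshold in bp, exclusive, applied to merged
#'   intervals.
#' @param merge_gap Maximum gap in bp between kept segments that are merged
#'   before the size filter.
#' @return A list of class `seed_params`.
#' @seealso [seed_preset()] for the shipped cohort presets.
#' @export
seed_params <- function(cn_min, size_min, merge_gap = 300000) {
  stopifnot(cn_min > 0, size_min > 0, merge_gap >= 0)
  structure(list(cn_min = cn_min, size_min = size_min, merge_gap = merge_gap),
            class = "seed_params")
}

#' Named cohort presets for seed calling
#'
#' `cambridge`: CN > 4.5, size > 10 kbp; `fhcc_tumour`: CN > 4.3, size >
#' 50 kbp; `fhcc_normal`: CN > 4.0, size > 10 kbp; `tcga`: CN > 4.5,
#' size > 50 kbp.
#'
#' @param name Preset name.
#' @export
seed_preset <- function(name = c("cambridge", "fhcc_tumour", "fhcc_normal",
                                 "tcga")) {
  switch(match.arg(name),
         cambridge = seed_params(4.5, 10000),
         fhcc_tumour = seed_params(4.3, 50000),
         fhcc_normal = seed_params(4.0, 10000),
         tcga = seed_params(4.5, 50000))
}

#' Read a copy-number segment table
#'
#' Tab-delimited with a header; requires columns `chromosome`, `start`,
#' `end` and either an absolute copy number column (`cn`) or a `log2` ratio
#' column, selected by `value`. Log2 ratios are converted assuming a diploid
#' baseline (CN = 2 * 2^log2). Coordinates are 1-based inclusive.
#'
#' @param path Segment file.
#' @param value `"cn"` or `"log2"`.
#' @param sample_id Optional sample label attached to the result.
#' @return Data frame with columns `chrom`, `start`, `end`,
#'   `total_copy_number`, `sample_id`.
#' @export
read_cns <- function(path, value = c("cn", "log2"), sample_id = NA_character_) {
  value <- match.arg(value)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end",
            if (value == "cn") "cn" else "log2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("segment file lacks columns: ", paste(missing, collapse = ", "))
  }
  cn <- if (value == "cn") df$cn else 2 * 2^df$log2
  out <- data.frame(chrom = as.character(df$chromosome),
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    total_copy_number = as.numeric(cn),
                    sample_id = sample_id, stringsAsFactors = FALSE)
  if (any(out$total_copy_number < 0)) stop("negative copy number in ", path)
  out
}

#' Call focal-amplification seed regions
#'
#' Filter order: keep segments with `total_copy_number > cn_min`, merge kept
#' segments on the same chromosome separated by at most `merge_gap` bp, then
#' drop merged intervals with length `<= size_min`.
#'
#' @param segments Data frame from [read_cns()] (one sample).
#' @param params A [seed_params()] or preset name accepted by
#'   [seed_preset()].
#' @return Sorted interval data frame of seed regions.
#' @export
call_seeds <- function(segments, params = seed_preset("cambridge")) {
  if (is.character(params)) params <- seed_preset(params)
  stopifnot(inherits(params, "seed_params"))
  if (nrow(segments) == 0) return(empty_intervals())
  keep <- segments[segments$total_copy_number > params$cn_min, , drop = FALSE]
  if (nrow(keep) == 0) return(empty_intervals())
  merged <- merge_intervals(keep[, c("chrom", "start", "end")],
                            max_gap = params$merge_gap)
  merged <- merged[(merged$end - merged$start + 1) > params$size_min, ,
                   drop = FALSE]
  rownames(merged) <- NULL
  sort_intervals(merged)
}
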