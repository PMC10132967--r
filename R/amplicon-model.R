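#' Amplicon breakpoint graphs and cycle decompositions
#'
#' An amplicon is a focally amplified genomic region described by a
#' breakpoint graph -- oriented sequence segments with estimated copy counts
#' plus concordant/discordant junction edges -- and by a cycle decomposition,
#' a weighted set of cyclic and linear walks through the graph segments that
#' explains the observed copy counts. Both are exchanged as plain-text files
#' (the `_graph.txt` / `_cycles.txt` dialects emitted by breakpoint-graph
#' reconstruction tools); this module provides the data structures and
#' round-tripping readers/writers.
#'
#' @name amplicon-model
NULL

#' Construct an amplicon breakpoint graph
#'
#' @param amplicon_id,sample_id Identifiers.
#' @param segments Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `copy_count` (>= 0) and optionally `coverage`.
#'   Segments must not overlap within one amplicon.
#' @param edges Data frame of breakpoint edges with columns `chrom1`,
#'   `pos1`, `side1`, `chrom2`, `pos2`, `side2`, `kind`
#'   (`"concordant"`/`"discordant"`), `copy_count`, `support`. `side` is
#'   `"head"` (3' segment boundary) or `"tail"` (5' boundary). Edges are
#'   unordered: an edge equals its endpoint-swapped form.
#' @return An object of class `amplicon_graph`.
#' @export
amplicon_graph <- function(amplicon_id, sample_id = NA_character_,
                           segments = empty_segments(),
                           edges = empty_edges()) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(segments) > 0) {
    if (any(segments$end < segments$start)) stop("segment end < start")
    if (any(segments$copy_count < 0)) stop("negative segment copy count")
    if (is.null(segments$coverage)) segments$coverage <- NA_real_
    gr <- as_granges(segments)
    if (sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr)))) <
        sum(as.numeric(GenomicRanges::width(gr)))) {
      stop("segments overlap within amplicon ", amplicon_id)
    }
  } else {
    segments <- empty_segments()
  }
  if (nrow(edges) > 0) {
    if (any(edges$copy_count < 0)) stop("negative edge copy count")
    validate_edges(edges, segments, amplicon_id)
    edges <- canonical_edges(edges)
  } else {
    edges <- empty_edges()
  }
  segments <- sort_intervals(segments)
  rownames(segments) <- NULL
  structure(list(amplicon_id = amplicon_id, sample_id = sample_id,
                 segments = segments, edges = edges),
            class = "amplicon_graph")
}

empty_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             copy_count = numeric(), coverage = numeric(),
             stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), side1 = character(),
             chrom2 = character(), pos2 = numeric(), side2 = character(),
             kind = character(), copy_count = numeric(), support = numeric(),
             stringsAsFactors = FALSE)
}

validate_edges <- function(edges, segments, amplicon_id) {
  bad_kind <- !edges$kind %in% c("concordant", "discordant")
  if (any(bad_kind)) stop("unknown edge kind: ", edges$kind[bad_kind][1])
  conc <- edges$kind == "concordant"
  if (any(conc)) {
    same_chrom <- edges$chrom1[conc] == edges$chrom2[conc]
    adjacent <- abs(edges$pos1[conc] - edges$pos2[conc]) == 1
    if (any(!(same_chrom & adjacent))) {
      stop("concordant edge endpoints must be adjacent reference positions")
    }
  }
  # discordant endpoints must coincide with a segment boundary (+- 1 bp)
  disc <- edges[edges$kind == "discordant", , drop = FALSE]
  if (nrow(disc) > 0 && nrow(segments) > 0) {
    on_boundary <- function(chrom, pos) {
      hit <- segments$chrom == chrom &
        (abs(segments$start - pos) <= 1 | abs(segments$end - pos) <= 1)
      any(hit)
    }
    ok <- mapply(on_boundary, disc$chrom1, disc$pos1) &
      mapply(on_boundary, disc$chrom2, disc$pos2)
    if (any(!ok)) {
      stop("discordant edge endpoint off segment boundaries in amplicon ",
           amplicon_id)
    }
  }
  invisible(TRUE)
}

# order the two endpoints of each edge so equality/hashing is symmetric
canonical_edges <- function(edges) {
  key1 <- paste(edges$chrom1, sprintf("%012.0f", edges$pos1), edges$side1)
  key2 <- paste(edges$chrom2, sprintf("%012.0f", edges$pos2), edges$side2)
  swap <- key2 < key1
  if (any(swap)) {
    tmp <- edges[swap, c("chrom1", "pos1", "side1")]
    edges[swap, c("chrom1", "pos1", "side1")] <-
      edges[swap, c("chrom2", "pos2", "side2")]
    edges[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  edges <- edges[order(edges$kind, edges$chrom1, edges$pos1, edges$side1,
                       edges$chrom2, edges$pos2, edges$side2), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

edge_keys <- function(edges) {
  edges <- canonical_edges(edges)
  paste(edges$chrom1, edges$pos1, edges$side1,
        edges$chrom2, edges$pos2, edges$side2, sep = "|")
}

#' @export
print.amplicon_graph <- function(x, ...) {
  cat(sprintf("<amplicon_graph> %s (sample %s): %d segments, %d edges (%d discordant)\n",
              x$amplicon_id, x$sample_id, nrow(x$segments), nrow(x$edges),
              sum(x$edges$kind == "discordant")))
  invisible(x)
}

#' Construct a cycle decomposition
#'
#' @param amplicon_id Identifier shared with the matching graph.
#' @param segments Data frame with columns `seg_id` (integer), `chrom`,
#'   `start`, `end`.
#' @param cycles Data frame with columns `cycle_id`, `weight` (copy count
#'   attributed to the walk, >= 0), `is_cyclic` (logical) and `segments`
#'   (list column of signed segment tokens such as `c("1+", "2-")`,
#'   excluding the linear-walk `0` sentinels).
#' @return An object of class `decomposition`.
#' @export
decomposition <- function(amplicon_id, segments, cycles) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (anyDuplicated(segments$seg_id)) stop("duplicate segment id in decomposition")
  if (nrow(cycles) > 0) {
    if (any(cycles$weight < 0)) stop("negative cycle weight")
    used <- unique(unlist(lapply(cycles$segments, signed_ids)))
    missing <- setdiff(used, segments$seg_id)
    if (length(missing) > 0) {
      stop("cycle references undefined segment id: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(amplicon_id = amplicon_id, segments = segments,
                 cycles = cycles), class = "decomposition")
}

signed_ids <- function(tokens) as.integer(sub("[+-]$", "", tokens))

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s: %d segments, %d walks (%d cyclic)\n",
              x$amplicon_id, nrow(x$segments), nrow(x$cycles),
              sum(x$cycles$is_cyclic)))
  invisible(x)
}

# genomic footprint (interval df) of one walk within a decomposition
cycle_footprint <- function(decomp, tokens) {
  ids <- signed_ids(tokens)
  seg <- decomp$segments[match(ids, decomp$segments$seg_id), , drop = FALSE]
  iv_merge_base(seg[, c("chrom", "start", "end")])
}

# ---------------------------------------------------------------------------
# graph file dialect
# ---------------------------------------------------------------------------

parse_breakend <- function(token, lineno) {
  m <- regmatches(token, regexec("^([^:]+):([0-9]+)([+-])$", token))[[1]]
  if (length(m) != 4) stop("malformed coordinate '", token, "' at line ", lineno)
  list(chrom = m[2], pos = as.numeric(m[3]),
       side = if (m[4] == "+") "head" else "tail")
}

#' Read an amplicon breakpoint-graph file
#'
#' Records are tab-delimited with the first token a type keyword:
#' `sequence <chrom>:<start>- <chrom>:<end>+ <copy_count> [<coverage> <size>
#' <reads>]` and `concordant`/`discordant
#' `<chrom1>:<pos1><dir>-><chrom2>:<pos2><dir> <copy_count> <read_support>`
#' where `+` marks the head (3') side of a breakend and `-` the tail.
#' Header lines are ignored and unknown record types are skipped with a
#' warning (the dialect has evolved across tool versions).
#'
#' @param path Graph file.
#' @param amplicon_id,sample_id Optional identifiers; by default derived
#'   from the file name (`<sample>_<amplicon>_graph.txt`).
#' @return An [amplicon_graph()].
#' @export
read_graph_file <- function(path, amplicon_id = NULL, sample_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty graph file: ", path)
  if (is.null(amplicon_id)) {
    amplicon_id <- sub("_graph\\.txt$", "", basename(path))
  }
  if (is.null(sample_id)) sample_id <- sub("_amplicon[0-9]+$", "", amplicon_id)

  seg_rows <- list()
  edge_rows <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    kind <- tok[1]
    if (kind == "sequence") {
      a <- parse_breakend(tok[2], i)
      b <- parse_breakend(tok[3], i)
      cn <- suppressWarnings(as.numeric(tok[4]))
      if (is.na(cn) || cn < 0) stop("bad copy count at line ", i)
      if (b$pos < a$pos) stop("sequence end < start at line ", i)
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        chrom = a$chrom, start = a$pos, end = b$pos, copy_count = cn,
        coverage = if (length(tok) >= 5) suppressWarnings(as.numeric(tok[5])) else NA_real_,
        stringsAsFactors = FALSE)
    } else if (kind %in% c("concordant", "discordant")) {
      ends <- strsplit(tok[2], "->", fixed = TRUE)[[1]]
      if (length(ends) != 2) stop("malformed edge at line ", i)
      a <- parse_breakend(ends[1], i)
      b <- parse_breakend(ends[2], i)
      cn <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(cn) || cn < 0) stop("bad copy count at line ", i)
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        chrom1 = a$chrom, pos1 = a$pos, side1 = a$side,
        chrom2 = b$chrom, pos2 = b$pos, side2 = b$side,
        kind = kind, copy_count = cn,
        support = if (length(tok) >= 4) suppressWarnings(as.numeric(tok[4])) else NA_real_,
        stringsAsFactors = FALSE)
    } else if (grepl("Edge:", kind, fixed = TRUE) || i == 1) {
      # header line: silently ignored
    } else {
      warning("skipping unknown graph record type '", kind, "' at line ", i)
    }
  }
  if (length(seg_rows) == 0 && length(edge_rows) == 0) {
    stop("graph file contains no records: ", path)
  }
  amplicon_graph(amplicon_id, sample_id,
                 segments = do.call(rbind, seg_rows),
                 edges = if (length(edge_rows)) do.call(rbind, edge_rows) else empty_edges())
}

#' Write an amplicon breakpoint-graph file
#'
#' Deterministic output: segments sorted by coordinate, then edges in
#' canonical order. Round-trips through [read_graph_file()].
#'
#' @param graph An [amplicon_graph()].
#' @param path Output file.
#' @export
write_graph_file <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("SequenceEdge: StartPosition, EndPosition,",
                   "PredictedCopyCount, AverageCoverage"), con)
  seg <- sort_intervals(graph$segments)
  for (i in seq_len(nrow(seg))) {
    writeLines(sprintf("sequence\t%s:%s-\t%s:%s+\t%s\t%s",
                       seg$chrom[i], format_int(seg$start[i]),
                       seg$chrom[i], format_int(seg$end[i]),
                       format_cn(seg$copy_count[i]),
                       if (is.na(seg$coverage[i])) "0.000000" else format_cn(seg$coverage[i])),
               con)
  }
  writeLines("BreakpointEdge: StartPosition->EndPosition, PredictedCopyCount, NumberOfReadPairs", con)
  ed <- canonical_edges(graph$edges)
  side_chr <- function(s) ifelse(s == "head", "+", "-")
  for (i in seq_len(nrow(ed))) {
    writeLines(sprintf("%s\t%s:%s%s->%s:%s%s\t%s\t%s",
                       ed$kind[i],
                       ed$chrom1[i], format_int(ed$pos1[i]), side_chr(ed$side1[i]),
                       ed$chrom2[i], format_int(ed$pos2[i]), side_chr(ed$side2[i]),
                       format_cn(ed$copy_count[i]),
                       format_int(ifelse(is.na(ed$support[i]), 0, ed$support[i]))),
               con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# cycles file dialect
# ---------------------------------------------------------------------------

#' Read a cycle-decomposition file
#'
#' Dialect: optional `Interval <id> <chrom> <start> <end>` lines,
#' `Segment <id> <chrom> <start> <end>` definitions, and walk records
#' `Cycle=<k>;Copy_count=<w>;Segments=<id><sign>,...` where segment id `0`
#' is the boundary sentinel of a linear (non-closing) walk.
#'
#' @param path Cycles file.
#' @param amplicon_id Optional; derived from the file name by default.
#' @return A [decomposition()].
#' @export
read_cycles_file <- function(path, amplicon_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(amplicon_id)) {
    amplicon_id <- sub("_cycles\\.txt$", "", basename(path))
  }
  seg_rows <- list()
  cyc_rows <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (tok[1] == "Segment") {
      id <- as.integer(tok[2])
      if (any(vapply(seg_rows, function(r) r$seg_id == id, logical(1)))) {
        stop("duplicate segment id ", id, " at line ", i)
      }
      start <- as.numeric(tok[4]); end <- as.numeric(tok[5])
      if (is.na(start) || is.na(end) || end < start) {
        stop("malformed Segment record at line ", i)
      }
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        seg_id = id, chrom = tok[3], start = start, end = end,
        stringsAsFactors = FALSE)
    } else if (grepl("^Cycle=", tok[1])) {
      fields <- strsplit(tok[1], ";", fixed = TRUE)[[1]]
      kv <- strsplit(fields, "=", fixed = TRUE)
      vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      segs <- strsplit(vals[["Segments"]], ",", fixed = TRUE)[[1]]
      ids <- signed_ids(segs)
      is_cyclic <- !any(ids == 0)
      segs <- segs[ids != 0]
      cyc_rows[[length(cyc_rows) + 1]] <- data.frame(
        cycle_id = as.integer(vals[["Cycle"]]),
        weight = as.numeric(vals[["Copy_count"]]),
        is_cyclic = is_cyclic, stringsAsFactors = FALSE)
    cyc_rows[[length(cyc_rows)]]$segments <- I(list(segs))
    } else if (tok[1] == "Interval") {
      # interval summary lines carry no information beyond the segments
    } else {
      warning("skipping unknown cycles record at line ", i)
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(seg_id = integer(), chrom = character(), start = numeric(),
               end = numeric(), stringsAsFactors = FALSE)
  cycles <- if (length(cyc_rows)) do.call(rbind, cyc_rows) else
    data.frame(cycle_id = integer(), weight = numeric(),
               is_cyclic = logical(), segments = I(list()))
  decomposition(amplicon_id, segments, cycles)
}

#' Write a cycle-decomposition file
#'
#' Deterministic output: segments by coordinate, walks by descending weight.
#'
#' @param decomp A [decomposition()].
#' @param path Output file.
#' @export
write_cycles_file <- function(decomp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seg <- decomp$segments[order(decomp$segments$chrom, decomp$segments$start), ,
                         drop = FALSE]
  ivl <- merge_intervals(seg[, c("chrom", "start", "end")], max_gap = 0)
  for (i in seq_len(nrow(ivl))) {
    writeLines(sprintf("Interval\t%d\t%s\t%s\t%s", i, ivl$chrom[i],
                       format_int(ivl$start[i]), format_int(ivl$end[i])), con)
  }
  for (i in seq_len(nrow(seg))) {
    writeLines(sprintf("Segment\t%d\t%s\t%s\t%s", seg$seg_id[i], seg$chrom[i],
                       format_int(seg$start[i]), format_int(seg$end[i])), con)
  }
  cyc <- decomp$cycles
  ord <- order(-cyc$weight, cyc$cycle_id)
  cyc <- cyc[ord, , drop = FALSE]
  for (i in seq_len(nrow(cyc))) {
    toks <- cyc$segments[[i]]
    if (!cyc$is_cyclic[i]) toks <- c("0+", toks, "0-")
    writeLines(sprintf("Cycle=%d;Copy_count=%s;Segments=%s", i,
                       format_cn(cyc$weight[i]), paste(toks, collapse = ",")),
               con)
  }
  invisible(path)
}

#' Amplified intervals of a breakpoint graph
#'
#' Returns the merged, sorted genomic footprint of all graph segments whose
#' copy count reaches `cn_threshold`; intervals separated by at most 1 bp
#' are merged.
#'
#' @param graph An [amplicon_graph()].
#' @param cn_threshold Copy-number threshold (segments at or above are kept).
#' @return Sorted, non-overlapping interval data frame (possibly empty).
#' @export
amplified_intervals <- function(graph, cn_threshold = 4.5) {
  stopifnot(cn_threshold > 0)
  seg <- graph$segments[graph$segments$copy_count >= cn_threshold, , drop = FALSE]
  if (nrow(seg) == 0) return(empty_intervals())
  merge_intervals(seg[, c("chrom", "start", "end")], max_gap = 1)
}
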