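#' Genes carried on focal amplifications
#'
#' A gene is called as carried on an amplicon when its average copy number
#' over the gene body reaches 4.5 and its 5' end is intact: the 5'-most
#' base lies inside an amplified interval and no discordant junction falls
#' within the first kilobase of the gene (the window is configurable).
#' Gene-body copy number is the length-weighted mean of the overlapping
#' graph-segment copy counts, with uncovered bases assumed diploid (CN 2).
#'
#' @name gene-annotation
NULL

#' Read gene models
#'
#' Tab-delimited, no header: chrom, start, end, name, strand. Coordinates
#' are 1-based inclusive. The 5' position is `start` on the + strand and
#' `end` on the - strand.
#'
#' @param path Gene model file.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `five_prime_pos`.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "strand"))
  gene_models(df$chrom, df$start, df$end, df$name, df$strand)
}

#' Construct gene models
#' @param chrom,start,end,name,strand Vectors of gene coordinates (1-based
#'   inclusive), symbols and strands.
#' @export
gene_models <- function(chrom, start, end, name, strand) {
  df <- genomic_intervals(chrom, start, end)
  df$name <- as.character(name)
  df$strand <- as.character(strand)
  stopifnot(all(df$strand %in% c("+", "-")))
  df$five_prime_pos <- ifelse(df$strand == "+", df$start, df$end)
  df
}

#' Call genes on one amplicon
#'
#' @param amp A `classified_amplicon`.
#' @param genes Gene models from [read_gene_bed()]/[gene_models()].
#' @param oncogenes,immunomodulatory Character vectors of gene symbols used
#'   to flag calls.
#' @param cn_min Minimum mean gene copy number for a call (default 4.5,
#'   inclusive).
#' @param five_prime_window 5' window in bp within which a discordant
#'   junction voids the call (default 1000).
#' @return Data frame of gene calls (possibly zero rows): `gene`,
#'   `amplicon_id`, `sample_id`, `mean_copy_number`, `five_prime_intact`,
#'   `on_ecdna`, `is_oncogene`, `is_immunomodulatory`.
#' @export
genes_on_amplicon <- function(amp, genes, oncogenes = character(),
                              immunomodulatory = character(),
                              cn_min = 4.5, five_prime_window = 1000) {
  empty <- data.frame(gene = character(), amplicon_id = character(),
                      sample_id = character(), mean_copy_number = numeric(),
                      five_prime_intact = logical(), on_ecdna = logical(),
                      is_oncogene = logical(), is_immunomodulatory = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0 || nrow(amp$amplified) == 0) return(empty)
  cand <- genes[vapply(seq_len(nrow(genes)), function(i)
    intervals_overlap_any(genes[i, c("chrom", "start", "end")],
                          amp$amplified), logical(1)), , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  disc <- amp$graph$edges[amp$graph$edges$kind == "discordant", , drop = FALSE]
  bp <- rbind(data.frame(chrom = disc$chrom1, pos = disc$pos1),
              data.frame(chrom = disc$chrom2, pos = disc$pos2))

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    g <- cand[i, ]
    glen <- g$end - g$start + 1
    seg <- amp$graph$segments
    seg <- seg[seg$chrom == g$chrom & seg$end >= g$start & seg$start <= g$end, ,
               drop = FALSE]
    ov <- if (nrow(seg) == 0) 0 else
      pmin(seg$end, g$end) - pmax(seg$start, g$start) + 1
    covered <- sum(ov)
    mean_cn <- (sum(ov * seg$copy_count) + (glen - covered) * 2) / glen

    fp_in_amp <- intervals_overlap_any(
      genomic_intervals(g$chrom, g$five_prime_pos, g$five_prime_pos),
      amp$amplified)
    d <- if (g$strand == "+") bp$pos - g$five_prime_pos else
      g$five_prime_pos - bp$pos
    bp_hit <- any(bp$chrom == g$chrom & d > 0 & d < five_prime_window)
    intact <- fp_in_amp && !bp_hit

    data.frame(gene = g$name, amplicon_id = amp$amplicon_id,
               sample_id = amp$sample_id, mean_copy_number = mean_cn,
               five_prime_intact = intact,
               on_ecdna = amp$amplicon_class == "ecDNA",
               is_oncogene = g$name %in% oncogenes,
               is_immunomodulatory = g$name %in% immunomodulatory,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$mean_copy_number >= cn_min & out$five_prime_intact, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class oncogene summary
#'
#' @param amplicons List of classified amplicons.
#' @param calls Gene-call data frame from [genes_on_amplicon()] covering the
#'   same amplicons.
#' @return Data frame with one row per amplicon class present plus a
#'   `non_ecDNA_fsCNA` aggregate row: `n_amplicons`, `n_unique_oncogenes`,
#'   `oncogenes_per_amplicon`, `frac_multi_oncogene`, `max_oncogene_cn`.
#' @export
oncogene_summary <- function(amplicons, calls) {
  empty <- data.frame(class = character(), n_amplicons = integer(),
                      n_unique_oncogenes = integer(),
                      oncogenes_per_amplicon = numeric(),
                      frac_multi_oncogene = numeric(),
                      max_oncogene_cn = numeric(), stringsAsFactors = FALSE)
  if (length(amplicons) == 0) return(empty)
  tab <- classification_table(amplicons)
  onc <- calls[calls$is_oncogene, , drop = FALSE]
  one <- function(label, ids) {
    sub <- onc[onc$amplicon_id %in% ids, , drop = FALSE]
    per_amp <- table(factor(sub$amplicon_id, levels = unique(ids)))
    data.frame(class = label, n_amplicons = length(ids),
               n_unique_oncogenes = length(unique(sub$gene)),
               oncogenes_per_amplicon = if (length(ids) > 0)
                 length(unique(sub$gene)) / length(ids) else NA_real_,
               frac_multi_oncogene = if (length(ids) > 0)
                 mean(per_amp >= 2) else NA_real_,
               max_oncogene_cn = if (nrow(sub) > 0)
                 max(sub$mean_copy_number) else NA_real_,
               stringsAsFactors = FALSE)
  }
  classes <- intersect(AMPLICON_CLASSES, unique(tab$class))
  out <- do.call(rbind, lapply(classes, function(cl)
    one(cl, tab$amplicon_id[tab$class == cl])))
  non_ec <- tab$amplicon_id[tab$class != "ecDNA"]
  if (length(non_ec) > 0) out <- rbind(out, one("non_ecDNA_fsCNA", non_ec))
  rownames(out) <- NULL
  out
}
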