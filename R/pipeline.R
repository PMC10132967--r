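#' End-to-end pipeline
#'
#' [load_cohort()] reads a cohort directory (simulated or assembled in the
#' same layout) and runs seed calling and amplicon classification for every
#' sample; [run_pipeline()] orchestrates the full analysis -- simulate,
#' seed, classify, similarity/complexity, gene calls, association
#' statistics -- and writes all tabular outputs plus a run manifest. Every
#' stage is a pure function of (inputs, configuration, seed), so re-running
#' with the same seed reproduces the output tree byte for byte.
#'
#' @name pipeline
NULL

#' Load and classify a cohort directory
#'
#' Expects the layout written by [simulate_cohort()]: `samples.tsv`,
#' `histology.tsv`, `genome.tsv`, `genes.tsv`, gene-list files and
#' `samples/<sample_id>/` directories with a `.cns` segment file and
#' graph/cycles file pairs.
#'
#' @param dir Cohort directory.
#' @param seed_params A [seed_params()] object or preset name for seed
#'   calling.
#' @param classifier A [classifier_params()].
#' @param window_cm Histology pairing window in cm.
#' @return List with `samples` (list of per-sample records carrying
#'   metadata, paired histology, seed regions and deduplicated classified
#'   amplicons), `table` (per-sample summary data frame), `amplicons`
#'   (flat list), `genome`, `genes`, `oncogenes`, `immunomodulatory`.
#' @export
load_cohort <- function(dir, seed_params = seed_preset("fhcc_tumour"),
                        classifier = classifier_params(), window_cm = 1) {
  if (is.character(seed_params)) seed_params <- seed_preset(seed_params)
  meta <- utils::read.delim(file.path(dir, "samples.tsv"),
                            stringsAsFactors = FALSE)
  hist <- utils::read.delim(file.path(dir, "histology.tsv"),
                            stringsAsFactors = FALSE)
  meta <- pair_histology(meta, hist, window_cm = window_cm)
  gtab <- utils::read.delim(file.path(dir, "genome.tsv"),
                            stringsAsFactors = FALSE)
  genome <- stats::setNames(as.numeric(gtab$length), gtab$chrom)
  genes <- read_gene_bed(file.path(dir, "genes.tsv"))
  onc <- readLines(file.path(dir, "oncogenes.txt"))
  imm <- readLines(file.path(dir, "immunomodulatory.txt"))

  samples <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    d <- file.path(dir, "samples", sid)
    cns <- read_cns(file.path(d, paste0(sid, ".cns")), sample_id = sid)
    seeds <- call_seeds(cns, seed_params)
    gfiles <- sort(list.files(d, pattern = "_graph\\.txt$",
                              full.names = TRUE))
    amps <- lapply(gfiles, function(gf) {
      cf <- sub("_graph\\.txt$", "_cycles.txt", gf)
      classify_amplicon(read_graph_file(gf), read_cycles_file(cf), classifier)
    })
    amps <- deduplicate_amplicons(amps)
    status <- sample_ecdna_status(amps)
    samples[[i]] <- list(
      sample_id = sid, patient_id = meta$patient_id[i],
      group = meta$group[i], time_point = meta$time_point[i],
      level_cm = meta$level_cm[i],
      histology_on_level = meta$histology_on_level[i],
      histology_windowed = meta$histology_windowed[i],
      seeds = seeds, amplicons = amps,
      ecdna_positive = status$is_positive, n_species = status$n_species)
  }
  tab <- meta
  tab$ecdna_positive <- vapply(samples, function(s) s$ecdna_positive,
                               logical(1))
  tab$n_ecdna_species <- vapply(samples, function(s) s$n_species, integer(1))
  list(samples = samples, table = tab,
       amplicons = unlist(lapply(samples, function(s) s$amplicons),
                          recursive = FALSE),
       genome = genome, genes = genes, oncogenes = onc,
       immunomodulatory = imm)
}

#' Run the full pipeline
#'
#' Stages, in order: simulate the cohort (`cohort/`), call seeds and
#' classify every sample's amplicons, score within-patient ecDNA
#' similarity and call clonal pairs, annotate amplicon-borne genes, pair
#' histology and compute the association statistics. All outputs are
#' written under `results/` with fixed names and a `manifest.json`
#' (configuration snapshot, package version, seed, per-file checksums) is
#' left at the top level.
#'
#' @param config A [sim_config()].
#' @param outdir Run directory.
#' @param alpha Significance level for clonal-pair calling.
#' @param n_null Null draws for the empirical similarity p-value.
#' @return Invisibly, a list with `manifest`, `cohort` (the [load_cohort()]
#'   result), `classification`, `gene_calls`, `oncogene_summary`,
#'   `clonal_pairs`, `tables`, `stats`.
#' @export
run_pipeline <- function(config, outdir, alpha = 0.05, n_null = 1000) {
  stopifnot(inherits(config, "sim_config"))
  cohort_dir <- file.path(outdir, "cohort")
  res_dir <- file.path(outdir, "results")
  sim <- simulate_cohort(config, cohort_dir)
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

  preset <- if (config$design == "fhcc") "fhcc_tumour" else "cambridge"
  cohort <- load_cohort(cohort_dir, seed_params = preset)

  # classification + complexity
  cls <- classification_table(cohort$amplicons)
  write_tsv(num_format(cls, c("max_copy_number", "complexity_bits")),
            file.path(res_dir, "classification.tsv"))
  status <- cohort$table
  write_tsv(status, file.path(res_dir, "sample_status.tsv"))
  seed_rows <- do.call(rbind, lapply(cohort$samples, function(s) {
    if (nrow(s$seeds) == 0) return(NULL)
    cbind(s$seeds, name = s$sample_id)
  }))
  if (!is.null(seed_rows)) write_bed(seed_rows,
                                     file.path(res_dir, "seeds.bed"))

  # gene calls
  calls <- do.call(rbind, lapply(cohort$amplicons, function(a)
    genes_on_amplicon(a, cohort$genes, cohort$oncogenes,
                      cohort$immunomodulatory)))
  if (is.null(calls)) calls <- genes_on_amplicon(
    list(amplified = empty_intervals()), cohort$genes)
  write_tsv(num_format(calls, "mean_copy_number"),
            file.path(res_dir, "gene_calls.tsv"))
  osum <- oncogene_summary(cohort$amplicons, calls)
  write_tsv(num_format(osum, c("oncogenes_per_amplicon",
                               "frac_multi_oncogene", "max_oncogene_cn")),
            file.path(res_dir, "oncogene_summary.tsv"))

  # clonal pairs (longitudinal designs only)
  pairs <- if (config$design == "fhcc") {
    find_clonal_pairs(cohort$samples, alpha = alpha, n_null = n_null,
                      seed = config$seed, genome = cohort$genome)
  } else {
    find_clonal_pairs(list(), alpha = alpha)
  }
  write_tsv(num_format(pairs, c("genomic_jaccard", "breakpoint_jaccard",
                                "score", "p_value", "cn_a", "cn_b",
                                "cn_delta")),
            file.path(res_dir, "clonal_pairs.tsv"))

  # association statistics
  tables <- build_cohort_tables(status)
  stats <- cohort_stats_report(tables)
  write_tsv(num_format(stats, c("fisher_p", "odds_ratio", "ci_low",
                                "ci_high")),
            file.path(res_dir, "stats.tsv"))
  report <- list(
    tables = lapply(tables, function(t) list(counts = as.vector(t(t)))),
    statistics = stats)
  jsonlite::write_json(report, file.path(res_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(c(list.files(res_dir, full.names = TRUE, recursive = TRUE)))
  manifest <- list(
    package = "ecamplicon",
    version = as.character(utils::packageVersion("ecamplicon")),
    seed = config$seed, design = config$design,
    config = config[setdiff(names(config), c("seed", "design"))],
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      substring(files, nchar(outdir) + 2))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort, classification = cls,
                 gene_calls = calls, oncogene_summary = osum,
                 clonal_pairs = pairs, tables = tables, stats = stats))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# render numeric columns with fixed precision so outputs are byte-stable
num_format <- function(df, cols) {
  for (cl in intersect(cols, names(df))) {
    df[[cl]] <- ifelse(is.na(df[[cl]]), "NA", sprintf("%.6g", df[[cl]]))
  }
  df
}
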