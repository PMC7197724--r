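# End-to-end pipeline entry points. These back the thin command-line script
# shipped at inst/cli/triofish.R; all outputs embed the package version, a
# configuration fingerprint and the seed, so a fixed seed reproduces every
# file byte for byte.

summary_header <- function(seed, config) {
  list(tool = "triofish",
       version = as.character(utils::packageVersion("triofish")),
       seed = as.integer(seed),
       config_hash = config_hash(config))
}

#' Prioritize variants from a VCF + annotation pair
#'
#' Reads the trio dataset, runs the full funnel ([run_models()]), ranks the
#' surviving candidates and writes the candidate report, the funnel JSON
#' sidecar and the ranked table.
#'
#' @param vcf_path,annotation_path input files (see [read_trio()]).
#' @param out_dir output directory (created if needed).
#' @param ped a [pedigree()].
#' @param rarity_cutoff passed to [run_models()].
#' @param thresholds passed to [rank_candidates()].
#' @param seed integer recorded in output headers.
#' @return the `candidate_report`, invisibly (with attribute `paths`).
#' @export
run_prioritize <- function(vcf_path, annotation_path, out_dir,
                           ped = pedigree(), rarity_cutoff = 0.01,
                           thresholds = prioritization_thresholds(),
                           seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_trio(vcf_path, annotation_path, ped)
  report <- run_models(records, ped, rarity_cutoff)
  ranked <- rank_candidates(report, thresholds)
  paths <- write_candidate_report(report,
                                  file.path(out_dir, "candidate_report.tsv"),
                                  ranked = ranked, seed = seed)
  attr(report, "paths") <- paths
  invisible(report)
}

#' Analyze a tracking export
#'
#' Parses the export, summarizes each animal over the protocol and writes
#' per-animal summaries plus the requested group contrasts.
#'
#' @param csv_path tracking export (see [read_tracking_export()]).
#' @param out_dir output directory.
#' @param protocol a [protocol_spec()].
#' @param contrasts list of `c(group_a, group_b)` pairs to compare on both
#'   speed and distance; defaults to none (summaries only).
#' @param level,variant passed to [compare_groups()].
#' @param seed integer recorded in output headers.
#' @return list with `summaries` and `comparisons`, invisibly.
#' @export
run_motility <- function(csv_path, out_dir, protocol = protocol_spec(),
                         contrasts = list(), level = "animal",
                         variant = "student", seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bins <- read_tracking_export(csv_path)
  if (nrow(bins) == 0L) stop("tracking export contains no usable rows")
  summaries <- summarize_larvae(bins, protocol)
  con <- file(file.path(out_dir, "larva_summaries.tsv"), "w")
  writeLines(provenance_lines(seed), con)
  utils::write.table(summaries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  comparisons <- list()
  for (ct in contrasts) {
    for (metric in c("swim_speed_mm_per_s", "total_distance_mm")) {
      comparisons[[length(comparisons) + 1L]] <-
        compare_groups(summaries, metric, ct[1], ct[2], level = level,
                       variant = variant)
    }
  }
  if (length(comparisons))
    write_comparison_table(comparisons,
                           file.path(out_dir, "group_comparisons.tsv"),
                           seed = seed)
  invisible(list(summaries = summaries, comparisons = comparisons))
}

#' Relative quantification from a Ct table
#'
#' Collapses technical replicates and computes 2^-ddCt fold changes for each
#' requested gene between two groups.
#'
#' @param csv_path long-format Ct table (see [read_qpcr_table()]).
#' @param out_dir output directory.
#' @param control_group,treated_group group labels.
#' @param genes genes to quantify; default all non-reference genes in the
#'   table.
#' @param reference_gene optional reference gene (see [delta_delta_ct()]).
#' @param qc_sd passed to [collapse_technical()].
#' @param variant t-test variant.
#' @param seed integer recorded in output headers.
#' @return list of `relative_expression` rows, invisibly.
#' @export
run_ddct <- function(csv_path, out_dir, control_group, treated_group,
                     genes = NULL, reference_gene = NULL, qc_sd = 0.5,
                     variant = "student", seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  measurements <- read_qpcr_table(csv_path)
  collapsed <- collapse_technical(measurements, qc_sd = qc_sd)
  if (is.null(genes))
    genes <- setdiff(unique(collapsed$gene), reference_gene)
  results <- lapply(genes, function(g)
    delta_delta_ct(collapsed, g, control_group, treated_group,
                   reference_gene = reference_gene, variant = variant))
  write_expression_table(results,
                         file.path(out_dir, "relative_expression.tsv"),
                         seed = seed)
  invisible(results)
}

#' Run the end-to-end demonstration pipeline
#'
#' From a single seed: simulates an annotated trio exome, a morphant
#' motility experiment (hypoactive knockdown group vs control), a PTZ
#' challenge experiment (treated vs untreated), and a qPCR plate; writes
#' every dataset, runs all three analyses, and writes a combined JSON
#' summary. Running twice with the same seed produces byte-identical
#' output directories.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @param n_background_variants background variants for the trio stage.
#' @param n_per_group animals per group for the behavior stages.
#' @return list with the per-stage results, invisibly.
#' @export
run_demo <- function(seed, out_dir, n_background_variants = 5000L,
                     n_per_group = 12L) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # Trio exome: simulate, write, read back, prioritize.
  trio_cfg <- trio_sim_config(n_background_variants = n_background_variants,
                              seed = seed)
  trio <- simulate_trio(trio_cfg)
  trio_dir <- file.path(out_dir, "trio")
  paths <- write_trio(trio, trio_dir)
  report <- run_prioritize(paths[["vcf"]], paths[["annotation"]], trio_dir,
                           ped = trio$pedigree, seed = seed)

  # Morphant motility: knockdown group at half activity vs control.
  beh_dir <- file.path(out_dir, "behavior")
  dir.create(beh_dir, recursive = TRUE, showWarnings = FALSE)
  track_cfg <- track_sim_config(n_per_group = n_per_group, seed = seed + 1L)
  tracks <- simulate_tracks(track_cfg)
  track_csv <- file.path(beh_dir, "tracking.csv")
  write_tracking_export(tracks$bins, track_csv, seed = seed + 1L)
  motility <- run_motility(track_csv, beh_dir, protocol = tracks$protocol,
                           contrasts = list(c("RC", "tbMO")),
                           seed = seed + 1L)

  # PTZ challenge: treated group at 2x speed / 6x distance vs untreated.
  ptz_cfg <- track_sim_config(n_per_group = n_per_group,
                              groups = c("NT", "PTZ"),
                              hypo_groups = character(),
                              ptz_groups = "PTZ",
                              ptz_speed_factor = 2, ptz_distance_factor = 6,
                              seed = seed + 2L)
  ptz_sim <- simulate_tracks(ptz_cfg)
  ptz_csv <- file.path(beh_dir, "tracking_ptz.csv")
  write_tracking_export(ptz_sim$bins, ptz_csv, seed = seed + 2L)
  ptz_bins <- read_tracking_export(ptz_csv)
  ptz_sum <- summarize_larvae(ptz_bins, ptz_sim$protocol)
  ptz <- ptz_response(ptz_sum, treated_label = "PTZ", untreated_label = "NT")
  write_comparison_table(ptz, file.path(beh_dir, "ptz_response.tsv"),
                         seed = seed + 2L)

  # qPCR: receptor-subunit panel with planted fold changes.
  qpcr_dir <- file.path(out_dir, "qpcr")
  dir.create(qpcr_dir, recursive = TRUE, showWarnings = FALSE)
  qpcr_cfg <- qpcr_sim_config(seed = seed + 3L)
  qpcr <- simulate_qpcr(qpcr_cfg)
  qpcr_csv <- file.path(qpcr_dir, "ct_table.csv")
  write_qpcr_table(qpcr$measurements, qpcr_csv, seed = seed + 3L)
  expression <- run_ddct(qpcr_csv, qpcr_dir, control_group = "RC",
                         treated_group = "tbMO", seed = seed + 3L)

  summary <- c(summary_header(seed, list(trio = unclass(trio_cfg),
                                         tracks = unclass(track_cfg),
                                         ptz = unclass(ptz_cfg),
                                         qpcr = unclass(qpcr_cfg))),
               list(candidate_genes = report$candidate_genes,
                    funnel = as.list(report$funnel),
                    morphant_distance_fold =
                      motility$comparisons[[2]]$fold_change,
                    ptz_speed_fold = ptz$speed$fold_change,
                    ptz_distance_fold = ptz$distance$fold_change,
                    qpcr_fold_changes = stats::setNames(
                      lapply(expression, function(r) r$fold_change),
                      vapply(expression, function(r) r$gene, character(1)))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trio = trio, report = report, motility = motility,
                 ptz = ptz, expression = expression))
}
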