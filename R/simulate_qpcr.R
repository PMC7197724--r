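# Seeded simulator of qPCR plates with planted log2 fold changes.

#' Configure a synthetic qPCR experiment
#'
#' Ct values are generated as
#' `baseline_ct - planted_log2fc[gene] * I(sample in treated group) +
#' N(0, ct_sd^2)` per biological sample, then replicated `n_technical` times
#' with independent `N(0, tech_sd^2)` technical noise. Higher expression
#' therefore means lower Ct, and a planted log2 fold change of +1 is
#' recovered by [delta_delta_ct()] as fold change 2.
#'
#' @param genes gene symbols on the plate.
#' @param groups group labels; samples are generated for every group.
#' @param treated_group the group receiving the planted fold changes; must
#'   be one of `groups`.
#' @param n_biological biological samples per group.
#' @param n_technical technical replicates per (sample, gene); >= 1.
#' @param planted_log2fc named numeric vector, gene -> planted log2 fold
#'   change (treated vs control); genes not named get 0.
#' @param baseline_ct control-group expected Ct.
#' @param ct_sd biological (per-sample) Ct SD in cycles; >= 0.
#' @param tech_sd technical replicate Ct SD in cycles; >= 0.
#' @param seed integer seed.
#' @return a `qpcr_sim_config` object.
#' @export
qpcr_sim_config <- function(genes = c("gabra2a", "gabra3", "gabra4", "gabra5",
                                      "gabra6a", "gabra6b", "gabrb2",
                                      "gabrg2"),
                            groups = c("RC", "tbMO"),
                            treated_group = "tbMO",
                            n_biological = 3L,
                            n_technical = 3L,
                            planted_log2fc = c(gabrb2 = -1, gabrg2 = -1,
                                               gabra6b = 1),
                            baseline_ct = 25,
                            ct_sd = 0.15,
                            tech_sd = 0.05,
                            seed = 1L) {
  if (!treated_group %in% groups)
    stop("treated_group \"", treated_group, "\" is not one of groups")
  if (length(planted_log2fc)) {
    if (is.null(names(planted_log2fc)) ||
        !all(names(planted_log2fc) %in% genes))
      stop("planted_log2fc must be named by genes on the plate")
  }
  if (n_technical < 1L) stop("n_technical must be >= 1")
  if (n_biological < 1L) stop("n_biological must be >= 1")
  if (ct_sd < 0 || tech_sd < 0) stop("ct_sd and tech_sd must be >= 0")
  fc <- stats::setNames(rep(0, length(genes)), genes)
  fc[names(planted_log2fc)] <- planted_log2fc
  structure(list(genes = genes, groups = groups,
                 treated_group = treated_group,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 planted_log2fc = fc, baseline_ct = baseline_ct,
                 ct_sd = ct_sd, tech_sd = tech_sd, seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR Ct table
#'
#' @param config a [qpcr_sim_config()].
#' @return list of class `qpcr_sim`: `measurements` (long data frame:
#'   `sample_id`, `group`, `gene`, `tech_rep`, `ct`), `truth` (per-gene
#'   planted log2 fold change and expected fold change), `config`.
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(n_biological = 3, seed = 2))
#' head(sim$measurements)
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(config$seed)
  rows <- list()
  for (g in config$groups) {
    treated <- g == config$treated_group
    for (i in seq_len(config$n_biological)) {
      sample_id <- sprintf("%s_%d", g, i)
      for (gene in config$genes) {
        mu <- config$baseline_ct -
          (if (treated) config$planted_log2fc[[gene]] else 0)
        ct_bio <- mu + stats::rnorm(1, 0, config$ct_sd)
        ct <- ct_bio + stats::rnorm(config$n_technical, 0, config$tech_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, group = g, gene = gene,
          tech_rep = seq_len(config$n_technical), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  truth <- data.frame(gene = config$genes,
                      planted_log2fc = unname(config$planted_log2fc),
                      expected_fold_change = 2^unname(config$planted_log2fc),
                      stringsAsFactors = FALSE)
  structure(list(measurements = measurements, truth = truth,
                 config = config),
            class = "qpcr_sim")
}
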