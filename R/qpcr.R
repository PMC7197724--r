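# Relative qPCR quantification: technical-replicate collapsing and Livak
# 2^-ddCt with biological-replicate statistics.

QPCR_COLUMNS <- c("sample_id", "group", "gene", "tech_rep", "ct")

#' Read a long-format Ct table
#'
#' CSV with columns `sample_id, group, gene, tech_rep, ct`; `#` comment
#' lines are ignored.
#'
#' @param path CSV path.
#' @return data frame of Ct measurements.
#' @export
read_qpcr_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(QPCR_COLUMNS, names(x))
  if (length(missing_cols))
    stop("qPCR table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x
}

#' Write a long-format Ct table
#'
#' @param measurements Ct data frame.
#' @param path output CSV path.
#' @param seed optional integer seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(measurements, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(measurements, con, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse technical replicates
#'
#' Arithmetic mean Ct per (sample, gene), with the replicate standard
#' deviation reported. A (sample, gene) whose replicate SD exceeds the QC
#' bound is flagged, not dropped.
#'
#' @param measurements Ct data frame (see [read_qpcr_table()]).
#' @param qc_sd QC bound on the technical-replicate SD, in cycles
#'   (default 0.5).
#' @return data frame with one row per (sample, gene): `sample_id`, `group`,
#'   `gene`, `ct_mean`, `ct_sd` (NA for a single replicate), `n_tech`,
#'   `qc_flag`.
#' @export
collapse_technical <- function(measurements, qc_sd = 0.5) {
  if (nrow(measurements) == 0L)
    return(data.frame(sample_id = character(), group = character(),
                      gene = character(), ct_mean = numeric(),
                      ct_sd = numeric(), n_tech = integer(),
                      qc_flag = logical(), stringsAsFactors = FALSE))
  key <- interaction(measurements$sample_id, measurements$gene, drop = TRUE)
  idx <- split(seq_len(nrow(measurements)), key)
  rows <- lapply(idx, function(i) {
    ct <- measurements$ct[i]
    s <- if (length(ct) > 1L) stats::sd(ct) else NA_real_
    data.frame(sample_id = measurements$sample_id[i[1]],
               group = measurements$group[i[1]],
               gene = measurements$gene[i[1]],
               ct_mean = mean(ct), ct_sd = s, n_tech = length(ct),
               qc_flag = !is.na(s) && s > qc_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$group, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per-sample dCt is the gene's collapsed Ct minus the reference gene's Ct
#' for the same sample; in input-normalized mode (no reference gene — total
#' RNA normalized by mass upstream) the raw gene Ct is used. Then
#' ddCt = mean dCt(treated) - mean dCt(control), fold change = 2^-ddCt, and
#' a two-tailed t-test compares the per-sample dCt values between groups
#' (Ct noise is approximately additive on the log2 scale, so the test is run
#' there, not on fold changes).
#'
#' Higher expression means lower Ct, so transcripts up in the treated group
#' give fold change > 1 and transcripts down give fold change < 1.
#'
#' @param collapsed output of [collapse_technical()].
#' @param gene target gene symbol.
#' @param control_group,treated_group group labels.
#' @param reference_gene optional endogenous reference gene; when given,
#'   every sample of both groups must have a Ct for it.
#' @param variant `"student"` (default) or `"welch"` t-test.
#' @return one-row data frame of class `relative_expression`: `gene`,
#'   `control_group`, `treated_group`, `n_control`, `n_treated`,
#'   `delta_delta_ct`, `log2_fc`, `fold_change`, `p_value`, `reference_gene`.
#' @export
delta_delta_ct <- function(collapsed, gene, control_group, treated_group,
                           reference_gene = NULL,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  dct_of <- function(grp) {
    g <- collapsed[collapsed$gene == gene & collapsed$group == grp, ,
                   drop = FALSE]
    if (is.null(reference_gene)) return(g$ct_mean)
    r <- collapsed[collapsed$gene == reference_gene & collapsed$group == grp, ,
                   drop = FALSE]
    i <- match(g$sample_id, r$sample_id)
    if (anyNA(i))
      stop("missing reference-gene measurements for sample(s): ",
           paste(g$sample_id[is.na(i)], collapse = ", "))
    g$ct_mean - r$ct_mean[i]
  }
  dct_control <- dct_of(control_group)
  dct_treated <- dct_of(treated_group)
  if (length(dct_control) < 2L || length(dct_treated) < 2L)
    stop("need >= 2 biological samples per group for gene ", gene)

  ddct <- mean(dct_treated) - mean(dct_control)
  if (stats::sd(dct_control) == 0 && stats::sd(dct_treated) == 0) {
    p <- if (ddct == 0) 1 else 0
  } else {
    p <- stats::t.test(dct_treated, dct_control,
                       var.equal = (variant == "student"))$p.value
  }
  structure(data.frame(gene = gene, control_group = control_group,
                       treated_group = treated_group,
                       n_control = length(dct_control),
                       n_treated = length(dct_treated),
                       delta_delta_ct = ddct, log2_fc = -ddct,
                       fold_change = 2^(-ddct), p_value = p,
                       reference_gene = reference_gene %||% NA_character_,
                       stringsAsFactors = FALSE),
            class = c("relative_expression", "data.frame"))
}

#' Write a relative-expression results table
#'
#' @param results a `relative_expression` row or list of them.
#' @param path output TSV path.
#' @param seed optional integer seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(results, path, seed = NULL) {
  if (inherits(results, "relative_expression")) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
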