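# Evidence aggregation: conservation and deleteriousness tallies and the
# candidate ranking, plus the CDS-coordinate codon mapping used to place a
# coding change on the protein.

#' Default evidence thresholds
#'
#' Per-tool cutoffs for calling a score "damaging" (prediction tools) or
#' "conserved" (conservation scores). Defaults follow common tool
#' conventions: CADD >= 20, PolyPhen2 >= 0.85, PROVEAN <= -2.5, SIFT <= 0.05,
#' MutationTaster >= 0.5; PhyloP >= 2, PhastCons >= 0.9, GERP >= 2. All are
#' overridable.
#'
#' @param cadd,polyphen2,provean,sift,mutationtaster prediction-tool cutoffs.
#' @param phylop,phastcons,gerp conservation cutoffs.
#' @return named list of thresholds.
#' @export
prioritization_thresholds <- function(cadd = 20, polyphen2 = 0.85,
                                      provean = -2.5, sift = 0.05,
                                      mutationtaster = 0.5,
                                      phylop = 2, phastcons = 0.9, gerp = 2) {
  list(cadd = cadd, polyphen2 = polyphen2, provean = provean, sift = sift,
       mutationtaster = mutationtaster, phylop = phylop,
       phastcons = phastcons, gerp = gerp)
}

#' Tally conservation and deleteriousness evidence for one variant
#'
#' Converts each populated score into a per-tool verdict and counts damaging
#' predictions (out of 5 tools) and conservation flags (out of 3 scores).
#' Missing scores contribute neither way. The rank key is the total tally,
#' tie-broken by CADD (higher first) then gene symbol.
#'
#' @param record a single-row trio record data frame.
#' @param thresholds from [prioritization_thresholds()].
#' @return object of class `evidence_summary`: list with `verdicts` (named
#'   character: damaging/benign/missing), `conservation` (named character:
#'   conserved/not_conserved/missing), `n_damaging_predictions`,
#'   `n_conserved_flags`, `tally` and `cadd`.
#' @export
score_candidate <- function(record, thresholds = prioritization_thresholds()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  verdict <- function(value, cutoff, damaging_when_low = FALSE) {
    if (is.na(value)) return("missing")
    hit <- if (damaging_when_low) value <= cutoff else value >= cutoff
    if (hit) "damaging" else "benign"
  }
  verdicts <- c(
    cadd = verdict(record$cadd, thresholds$cadd),
    polyphen2 = verdict(record$polyphen2, thresholds$polyphen2),
    provean = verdict(record$provean, thresholds$provean,
                      damaging_when_low = TRUE),
    sift = verdict(record$sift, thresholds$sift, damaging_when_low = TRUE),
    mutationtaster = verdict(record$mutationtaster, thresholds$mutationtaster))
  cons_verdict <- function(value, cutoff) {
    if (is.na(value)) return("missing")
    if (value >= cutoff) "conserved" else "not_conserved"
  }
  conservation <- c(phylop = cons_verdict(record$phylop, thresholds$phylop),
                    phastcons = cons_verdict(record$phastcons,
                                             thresholds$phastcons),
                    gerp = cons_verdict(record$gerp, thresholds$gerp))
  n_dam <- sum(verdicts == "damaging")
  n_cons <- sum(conservation == "conserved")
  structure(list(verdicts = verdicts, conservation = conservation,
                 n_damaging_predictions = n_dam,
                 n_conserved_flags = n_cons,
                 tally = n_dam + n_cons,
                 cadd = record$cadd),
            class = "evidence_summary")
}

#' Rank surviving candidates by evidence tally
#'
#' Scores every non-excluded model call and orders candidates by descending
#' evidence tally (damaging predictions + conservation flags), then
#' descending CADD, then gene symbol. A compound-het pair is ranked by the
#' better of its two members.
#'
#' @param report a `candidate_report` from [run_models()].
#' @param thresholds from [prioritization_thresholds()].
#' @return data frame with one row per retained call, ordered: `gene`,
#'   `model`, `key`, `key2`, `n_damaging_predictions`, `n_conserved_flags`,
#'   `tally`, `cadd`.
#' @export
rank_candidates <- function(report,
                            thresholds = prioritization_thresholds()) {
  stopifnot(inherits(report, "candidate_report"))
  calls <- report$calls[!report$calls$excluded_by_db, , drop = FALSE]
  cols <- c("gene", "model", "key", "key2", "n_damaging_predictions",
            "n_conserved_flags", "tally", "cadd")
  if (nrow(calls) == 0L) {
    out <- data.frame(gene = character(), model = character(),
                      key = character(), key2 = character(),
                      n_damaging_predictions = integer(),
                      n_conserved_flags = integer(), tally = integer(),
                      cadd = numeric(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  keys <- variant_key(report$records)
  summarize_call <- function(r) {
    members <- stats::na.omit(c(calls$key[r], calls$key2[r]))
    ev <- lapply(match(members, keys), function(i)
      score_candidate(report$records[i, , drop = FALSE], thresholds))
    best <- ev[[which.max(vapply(ev, function(e) e$tally, numeric(1)))]]
    cadds <- vapply(ev, function(e) e$cadd %||% NA_real_, numeric(1))
    cadd <- if (all(is.na(cadds))) NA_real_ else max(cadds, na.rm = TRUE)
    data.frame(gene = calls$gene[r], model = calls$model[r],
               key = calls$key[r], key2 = calls$key2[r],
               n_damaging_predictions = best$n_damaging_predictions,
               n_conserved_flags = best$n_conserved_flags,
               tally = best$tally, cadd = cadd, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(calls)), summarize_call))
  cadd_key <- ifelse(is.na(out$cadd), -Inf, out$cadd)
  out <- out[order(-out$tally, -cadd_key, out$gene, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out[, cols]
}

#' Codon index of a coding-sequence position
#'
#' Maps a 1-based coding-nucleotide (CDS) position to its 1-based codon
#' (amino-acid) index: positions 1-3 are codon 1, 4-6 codon 2, and so on.
#' Used to place a coding change such as c.875C>T at its residue (codon 292)
#' for, e.g., a transmembrane-domain check.
#'
#' @param cds_pos 1-based CDS position(s); vectorized.
#' @return integer codon index (or indices).
#' @examples
#' codon_of_cds_position(875)  # 292
#' @export
codon_of_cds_position <- function(cds_pos) {
  if (any(is.na(cds_pos)) || any(cds_pos < 1))
    stop("cds_pos must be >= 1")
  as.integer(floor((cds_pos - 1) / 3) + 1)
}
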