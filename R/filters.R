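# Funnel stages 1-2: functional-class filter and rarity filter.

#' Functional-class filter
#'
#' Keeps variants most likely to affect the gene product: nonsynonymous
#' coding variants, coding insertions/deletions shorter than 50 bp, and
#' splice-site variants. Everything else (synonymous, intronic, other, or
#' missing effect) is removed. The 50 bp bound is strict: an indel of exactly
#' 50 bp is removed.
#'
#' @param records trio record data frame with `effect` and `indel_len`.
#' @return list with `records` (kept subset) and `count` (number kept).
#' @export
filter_functional <- function(records) {
  eff <- records$effect
  keep <- !is.na(eff) &
    (eff == "nonsynonymous" |
       (eff == "coding_indel" & !is.na(records$indel_len) &
          records$indel_len < 50L) |
       eff == "splice_site")
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, count = nrow(kept))
}

#' Rarity filter
#'
#' Keeps rare variants: catalogued minor allele frequency strictly below
#' `cutoff`, or not catalogued at all (`dbsnp_maf` missing — an uncatalogued
#' variant cannot exceed the cutoff). A variant at exactly the cutoff is
#' removed.
#'
#' @param records trio record data frame.
#' @param cutoff rarity cutoff as a proportion in (0, 1); default 0.01 (1%).
#' @return list with `records` (kept subset) and `count` (number kept).
#' @export
filter_rare <- function(records, cutoff = 0.01) {
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0 && cutoff < 1))
    stop("cutoff must be a single proportion in (0, 1)")
  keep <- is.na(records$dbsnp_maf) | records$dbsnp_maf < cutoff
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, count = nrow(kept))
}
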