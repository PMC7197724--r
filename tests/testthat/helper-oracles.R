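# Independent oracles, deliberately written as explicit enumeration rather
# than reusing any package code path.

# Pooled-variance two-sample t-test from the textbook formula.
oracle_student_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive-enumeration implementation of the variant funnel: per-record
# loops over every predicate and a double loop over every pair per gene.
oracle_run_models <- function(records, proband_sex = "male",
                              rarity_cutoff = 0.01) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    e <- records$effect[i]
    keep[i] <- !is.na(e) &&
      (e == "nonsynonymous" || e == "splice_site" ||
         (e == "coding_indel" && records$indel_len[i] < 50))
  }
  rec <- records[keep, , drop = FALSE]
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    m <- rec$dbsnp_maf[i]
    keep[i] <- is.na(m) || m < rarity_cutoff
  }
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL

  n <- nrow(rec)
  chrom <- rec$chrom
  gene <- rec$gene
  gp <- rec$gt_proband
  gm <- rec$gt_mother
  gf <- rec$gt_father
  key <- paste(chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  present <- rec$present_dbsnp | rec$present_1kg | rec$present_evs |
    rec$present_exac
  hom_evidence <- (rec$hom_count_evs + rec$hom_count_exac) > 0
  hemi_evidence <- rec$hemi_count_exac > 0
  testable <- gp != "missing" & gm != "missing" & gf != "missing"

  calls <- list()
  add <- function(model, g, k1, k2, excluded) {
    calls[[length(calls) + 1L]] <<- data.frame(
      model = model, gene = g, key = k1, key2 = k2,
      excluded_by_db = excluded, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (!testable[i]) next
    sex_chrom <- chrom[i] %in% c("X", "Y")
    if (gm[i] == "ref" && gf[i] == "ref" &&
        (gp[i] == "het" || (sex_chrom && gp[i] == "hemi_alt")))
      add("de_novo", gene[i], key[i], NA_character_, present[i])
    if (!sex_chrom && gp[i] == "hom_alt" && gm[i] == "het" && gf[i] == "het")
      add("hom_recessive", gene[i], key[i], NA_character_, hom_evidence[i])
    if (proband_sex == "male" && chrom[i] == "X" && gp[i] == "hemi_alt" &&
        gm[i] == "het" && gf[i] == "ref")
      add("x_hemizygous", gene[i], key[i], NA_character_, hemi_evidence[i])
  }
  maternal <- testable & gp == "het" & gm %in% c("het", "hom_alt") & gf == "ref"
  paternal <- testable & gp == "het" & gf %in% c("het", "hom_alt") & gm == "ref"
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (gene[i] != gene[j]) next
        trans <- (maternal[i] && paternal[j]) || (maternal[j] && paternal[i])
        if (trans)
          add("comp_het", gene[i], key[i], key[j],
              hom_evidence[i] || hom_evidence[j])
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(model = character(), gene = character(), key = character(),
               key2 = character(), excluded_by_db = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$model, out$key, out$key2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sorted_calls <- function(calls) {
  out <- calls[order(calls$model, calls$key, calls$key2),
               c("model", "gene", "key", "key2", "excluded_by_db"),
               drop = FALSE]
  rownames(out) <- NULL
  out
}
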