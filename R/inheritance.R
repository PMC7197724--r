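# Funnel stage 3: inheritance-model tests on trio genotypes and the
# model-specific population-database exclusion rules.

empty_calls <- function() {
  data.frame(model = character(), gene = character(), key = character(),
             key2 = character(), excluded_by_db = logical(),
             exclusion_reason = character(), stringsAsFactors = FALSE)
}

new_calls <- function(model, records, idx, idx2 = NULL) {
  if (length(idx) == 0L) return(empty_calls())
  keys <- variant_key(records)
  data.frame(model = model, gene = records$gene[idx], key = keys[idx],
             key2 = if (is.null(idx2)) NA_character_ else keys[idx2],
             excluded_by_db = FALSE, exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

gt_testable <- function(records) {
  records$gt_proband != "missing" & records$gt_mother != "missing" &
    records$gt_father != "missing"
}

# Possible proband genotypes given parental genotypes (meiotic enumeration).
# Used to tally Mendelian-inconsistent configurations, which are never called
# under the recessive models. The de novo pattern (proband carrier, both
# parents ref) is by definition not a meiotic outcome and is NOT counted
# here: it is the dominant model's signature, not a genotyping artifact.
mendel_possible <- function(gt_mother, gt_father, chrom, proband_male) {
  alleles <- function(gt, hemi) switch(gt,
    ref = if (hemi) list(0L) else list(0L),
    het = list(0L, 1L),
    hom_alt = list(1L),
    hemi_alt = list(1L),
    missing = list(0L, 1L))
  on_x <- chrom == "X"
  mat <- unlist(alleles(gt_mother, FALSE))
  if (on_x && proband_male) {
    # Son receives X from mother only.
    return(unique(c("ref", "hemi_alt")[mat + 1L]))
  }
  pat <- unlist(alleles(gt_father, on_x))
  dos <- unique(outer(mat, pat, "+"))
  unique(dosage_to_gt(as.integer(dos)))
}

mendel_inconsistent <- function(records, ped) {
  male <- ped$proband_sex == "male"
  n <- nrow(records)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (records$gt_proband[i] == "missing" || records$gt_mother[i] == "missing" ||
        records$gt_father[i] == "missing") next
    de_novo_pattern <- records$gt_mother[i] == "ref" &&
      records$gt_father[i] == "ref" &&
      records$gt_proband[i] %in% c("het", "hemi_alt")
    if (de_novo_pattern) next
    poss <- mendel_possible(records$gt_mother[i], records$gt_father[i],
                            records$chrom[i], male)
    out[i] <- !(records$gt_proband[i] %in% poss)
  }
  out
}

#' De novo (dominant-model) calls
#'
#' One call per record where the proband carries a variant absent from both
#' parents: proband het (or, for a male proband on chrX/chrY,
#' hemizygous-alt) with both parents reference. Records with any missing
#' trio genotype are skipped.
#'
#' @param records trio record data frame.
#' @param ped a [pedigree()].
#' @return calls data frame (`model`, `gene`, `key`, `key2`,
#'   `excluded_by_db`, `exclusion_reason`).
#' @export
call_de_novo <- function(records, ped = pedigree()) {
  ok <- gt_testable(records)
  hemi_dn <- is_sex_chrom(records$chrom) & records$gt_proband == "hemi_alt"
  idx <- which(ok & (records$gt_proband == "het" | hemi_dn) &
                 records$gt_mother == "ref" & records$gt_father == "ref")
  new_calls("de_novo", records, idx)
}

#' Homozygous-recessive calls
#'
#' Autosomal records where the proband is homozygous-alt and both parents
#' are heterozygous carriers.
#'
#' @inheritParams call_de_novo
#' @return calls data frame.
#' @export
call_homozygous <- function(records, ped = pedigree()) {
  ok <- gt_testable(records)
  idx <- which(ok & !is_sex_chrom(records$chrom) &
                 records$gt_proband == "hom_alt" &
                 records$gt_mother == "het" & records$gt_father == "het")
  new_calls("hom_recessive", records, idx)
}

#' Compound-heterozygous calls
#'
#' For each gene, every unordered pair of distinct proband-het records in
#' trans configuration: one maternally transmitted (mother carrier, father
#' reference) and one paternally transmitted (father carrier, mother
#' reference). A transmitting parent may be het or hom-alt. In
#' `phase_mode = "permissive"` any two proband-het records in one gene
#' qualify (sensitivity analysis; no transmission-phase requirement).
#'
#' @inheritParams call_de_novo
#' @param phase_mode `"trans"` (default, standard genetic definition) or
#'   `"permissive"`.
#' @return calls data frame; `key`/`key2` are the pair members in genomic
#'   order.
#' @export
call_compound_het <- function(records, ped = pedigree(),
                              phase_mode = c("trans", "permissive")) {
  phase_mode <- match.arg(phase_mode)
  ok <- gt_testable(records)
  het <- ok & records$gt_proband == "het"
  maternal <- het & records$gt_mother %in% c("het", "hom_alt") &
    records$gt_father == "ref"
  paternal <- het & records$gt_father %in% c("het", "hom_alt") &
    records$gt_mother == "ref"
  calls <- list(empty_calls())
  for (g in unique(records$gene[het])) {
    if (is.na(g)) next
    in_gene <- !is.na(records$gene) & records$gene == g
    if (phase_mode == "trans") {
      mi <- which(in_gene & maternal)
      pi <- which(in_gene & paternal)
      if (length(mi) == 0L || length(pi) == 0L) next
      pairs <- expand.grid(a = mi, b = pi)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    } else {
      hi <- which(in_gene & het)
      if (length(hi) < 2L) next
      cmb <- utils::combn(hi, 2L)
      pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
    }
    if (nrow(pairs) == 0L) next
    first <- pmin(pairs$a, pairs$b)
    second <- pmax(pairs$a, pairs$b)
    dup <- duplicated(paste(first, second))
    calls[[length(calls) + 1L]] <-
      new_calls("comp_het", records, first[!dup], second[!dup])
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' X-linked hemizygous calls
#'
#' chrX records in a male proband: proband hemizygous-alt with a carrier
#' (het) mother and reference father. For a female proband the model does
#' not apply; an empty result is returned with a notice.
#'
#' @inheritParams call_de_novo
#' @return calls data frame.
#' @export
call_x_hemizygous <- function(records, ped = pedigree()) {
  if (ped$proband_sex != "male") {
    message("X-hemizygous model skipped: proband is female")
    return(empty_calls())
  }
  ok <- gt_testable(records)
  idx <- which(ok & records$chrom == "X" & records$gt_proband == "hemi_alt" &
                 records$gt_mother == "het" & records$gt_father == "ref")
  new_calls("x_hemizygous", records, idx)
}

#' Apply population-database exclusion rules
#'
#' Dominant (de novo) calls are excluded when the variant is present in any
#' database (dbSNP, 1000 Genomes, EVS, ExAC). Recessive autosomal calls
#' (homozygous and compound het) are excluded when homozygotes are found in
#' the databases (`hom_count_evs + hom_count_exac > 0`); a compound-het pair
#' is excluded if either member is. X-hemizygous calls are excluded when
#' hemizygotes are found (`hemi_count_exac > 0`). Database *presence* alone
#' does not exclude a recessive call.
#'
#' @param calls calls data frame from the `call_*` functions.
#' @param records the record data frame the calls reference.
#' @return `calls` with `excluded_by_db` and `exclusion_reason` set.
#' @export
apply_db_exclusion <- function(calls, records) {
  if (nrow(calls) == 0L) return(calls)
  keys <- variant_key(records)
  i1 <- match(calls$key, keys)
  i2 <- match(calls$key2, keys)
  if (anyNA(i1)) stop("call references a record key not present in records")

  flag <- function(x) !is.na(x) & x
  pos <- function(x) !is.na(x) & x > 0
  for (r in seq_len(nrow(calls))) {
    a <- i1[r]
    b <- i2[r]
    model <- calls$model[r]
    if (model == "de_novo") {
      hits <- c(dbSNP = flag(records$present_dbsnp[a]),
                `1000G` = flag(records$present_1kg[a]),
                EVS = flag(records$present_evs[a]),
                ExAC = flag(records$present_exac[a]))
      if (any(hits)) {
        calls$excluded_by_db[r] <- TRUE
        calls$exclusion_reason[r] <-
          paste0("present in ", paste(names(hits)[hits], collapse = ","))
      }
    } else if (model %in% c("hom_recessive", "comp_het")) {
      members <- c(a, if (model == "comp_het") b)
      hom <- pos(records$hom_count_evs[members] +
                   records$hom_count_exac[members])
      if (any(hom)) {
        calls$excluded_by_db[r] <- TRUE
        calls$exclusion_reason[r] <- "homozygotes in EVS/ExAC"
      }
    } else if (model == "x_hemizygous") {
      if (pos(records$hemi_count_exac[a])) {
        calls$excluded_by_db[r] <- TRUE
        calls$exclusion_reason[r] <- "hemizygotes in ExAC"
      }
    }
  }
  calls
}

#' Run the full variant-prioritization funnel
#'
#' Applies the functional-class filter, the rarity filter, the four
#' inheritance-model tests and the database exclusion rules, and aggregates
#' stage-by-stage funnel counts. Candidate genes are the genes of
#' non-excluded calls.
#'
#' Funnel stages: `total` -> `functional` -> `rare`, then bookkeeping counts
#' (`untestable` = records with a missing trio genotype, `inconsistent` =
#' Mendelian-impossible configurations, never called), per-model call counts,
#' and the final `candidate_genes` count.
#'
#' @param records trio record data frame (unfiltered; the filters are applied
#'   internally).
#' @param ped a [pedigree()].
#' @param rarity_cutoff passed to [filter_rare()].
#' @param phase_mode passed to [call_compound_het()].
#' @return object of class `candidate_report`: list with `calls`,
#'   `candidate_genes`, `funnel` (named integer vector), `records` (the
#'   post-filter records the calls reference) and `pedigree`.
#' @export
run_models <- function(records, ped = pedigree(), rarity_cutoff = 0.01,
                       phase_mode = c("trans", "permissive")) {
  phase_mode <- match.arg(phase_mode)
  n_total <- nrow(records)
  ff <- filter_functional(records)
  fr <- filter_rare(ff$records, rarity_cutoff)
  rec <- fr$records

  testable <- gt_testable(rec)
  inconsistent <- mendel_inconsistent(rec, ped)

  calls <- rbind(call_de_novo(rec, ped),
                 call_homozygous(rec, ped),
                 call_compound_het(rec, ped, phase_mode),
                 call_x_hemizygous(rec, ped))
  calls <- apply_db_exclusion(calls, rec)

  candidate_genes <- sort(unique(calls$gene[!calls$excluded_by_db]))
  n_model <- function(m) sum(calls$model == m)
  funnel <- c(total = n_total, functional = ff$count, rare = fr$count,
              untestable = sum(!testable), inconsistent = sum(inconsistent),
              de_novo = n_model("de_novo"),
              hom_recessive = n_model("hom_recessive"),
              comp_het = n_model("comp_het"),
              x_hemizygous = n_model("x_hemizygous"),
              candidate_genes = length(candidate_genes))
  structure(list(calls = calls, candidate_genes = candidate_genes,
                 funnel = funnel, records = rec, pedigree = ped),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Trio variant prioritization funnel\n")
  for (s in names(x$funnel)) cat(sprintf("  %-15s %d\n", s, x$funnel[[s]]))
  if (length(x$candidate_genes))
    cat("candidate genes:", paste(x$candidate_genes, collapse = ", "), "\n")
  invisible(x)
}
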