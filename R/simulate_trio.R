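# Seeded simulator of an annotated trio exome with planted causal variants
# among Mendelian-consistent background polymorphisms.

#' Configure a synthetic trio exome
#'
#' Describes a simulated annotated trio exome: background polymorphisms whose
#' genotypes follow Mendelian transmission from parents drawn at
#' Hardy-Weinberg proportions, plus causal variants planted under the four
#' inheritance models tested by [run_models()]. Planted variants are rare,
#' functionally severe, absent from population databases, and placed in
#' dedicated genes; background variants carry database evidence that excludes
#' them from candidacy (see the methods vignette).
#'
#' @param n_background_variants number of background polymorphisms.
#' @param n_genes number of background gene symbols; planted variants use
#'   additional dedicated genes.
#' @param planted named integer vector of planted variant counts; names from
#'   `de_novo`, `hom_recessive`, `comp_het`, `x_hemizygous`. `comp_het`
#'   counts variants (must be even; they are planted in trans pairs, one
#'   pair per gene).
#' @param proband_sex `"male"` or `"female"`; X-hemizygous plants require a
#'   male proband.
#' @param maf_rare_fraction fraction of background variants drawn from the
#'   rare minor-allele-frequency component (MAF in 0.0001-0.009); the rest
#'   are common (MAF in 0.05-0.5).
#' @param genotype_error_rate per-record probability that the proband
#'   genotype is replaced by a random different genotype. At 0 (default) the
#'   planted/background separation is exact.
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return a `trio_sim_config` object.
#' @seealso [simulate_trio()]
#' @export
trio_sim_config <- function(n_background_variants = 5000L,
                            n_genes = 1000L,
                            planted = c(de_novo = 1L, hom_recessive = 1L,
                                        comp_het = 2L, x_hemizygous = 1L),
                            proband_sex = c("male", "female"),
                            maf_rare_fraction = 0.2,
                            genotype_error_rate = 0,
                            seed = 1L) {
  proband_sex <- match.arg(proband_sex)
  full <- c(de_novo = 0L, hom_recessive = 0L, comp_het = 0L, x_hemizygous = 0L)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% names(full)))
      stop("planted must be a named vector with names among: ",
           paste(names(full), collapse = ", "))
    full[names(planted)] <- as.integer(planted)
  }
  if (any(full < 0L)) stop("planted counts must be >= 0")
  if (n_background_variants < 0L) stop("n_background_variants must be >= 0")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (full[["comp_het"]] %% 2L != 0L)
    stop("comp_het plants come in trans pairs: count must be even")
  if (full[["x_hemizygous"]] > 0L && proband_sex != "male")
    stop("x_hemizygous plants require proband_sex = \"male\"")
  if (maf_rare_fraction < 0 || maf_rare_fraction > 1)
    stop("maf_rare_fraction must be in [0, 1]")
  if (genotype_error_rate < 0 || genotype_error_rate > 1)
    stop("genotype_error_rate must be in [0, 1]")
  structure(list(n_background_variants = as.integer(n_background_variants),
                 n_genes = as.integer(n_genes),
                 planted = full,
                 proband_sex = proband_sex,
                 maf_rare_fraction = maf_rare_fraction,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "trio_sim_config")
}

# Canonical record constructor: fixes column order and types for the trio
# record model so the generator and the readers agree field-by-field.
new_trio_records <- function(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gene = character(), effect = character(),
                             indel_len = integer(),
                             gt_proband = character(), gt_mother = character(),
                             gt_father = character(),
                             dbsnp_maf = numeric(),
                             present_dbsnp = logical(), present_1kg = logical(),
                             present_evs = logical(), present_exac = logical(),
                             hom_count_evs = integer(), hom_count_exac = integer(),
                             hemi_count_exac = integer(),
                             phylop = numeric(), phastcons = numeric(),
                             gerp = numeric(), cadd = numeric(),
                             polyphen2 = numeric(), provean = numeric(),
                             sift = numeric(), mutationtaster = numeric()) {
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             ref = as.character(ref), alt = as.character(alt),
             gene = as.character(gene), effect = as.character(effect),
             indel_len = as.integer(indel_len),
             gt_proband = as.character(gt_proband),
             gt_mother = as.character(gt_mother),
             gt_father = as.character(gt_father),
             dbsnp_maf = as.numeric(dbsnp_maf),
             present_dbsnp = as.logical(present_dbsnp),
             present_1kg = as.logical(present_1kg),
             present_evs = as.logical(present_evs),
             present_exac = as.logical(present_exac),
             hom_count_evs = as.integer(hom_count_evs),
             hom_count_exac = as.integer(hom_count_exac),
             hemi_count_exac = as.integer(hemi_count_exac),
             phylop = as.numeric(phylop), phastcons = as.numeric(phastcons),
             gerp = as.numeric(gerp), cadd = as.numeric(cadd),
             polyphen2 = as.numeric(polyphen2), provean = as.numeric(provean),
             sift = as.numeric(sift), mutationtaster = as.numeric(mutationtaster),
             stringsAsFactors = FALSE)
}

# Draw a parental diploid allele dosage at HWE and transmit one allele.
transmit_allele <- function(dosage) {
  n <- length(dosage)
  out <- integer(n)
  out[dosage == 2L] <- 1L
  het <- dosage == 1L
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

dosage_to_gt <- function(dosage) c("ref", "het", "hom_alt")[dosage + 1L]

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate an annotated trio exome with planted causal variants
#'
#' Generates one record per variant (see [new_trio_records()] columns for the
#' record model) plus a truth table naming each planted variant's gene and
#' inheritance model.
#'
#' Background genotypes are always a possible meiotic outcome of the parental
#' genotypes (one allele transmitted per parent; the father is hemizygous on
#' chrX). Planted records follow the defining genotype pattern of their
#' model: de novo = proband het, both parents ref; homozygous recessive =
#' proband hom-alt, both parents het; compound het = two proband-het variants
#' in one gene, one transmitted from each parent; X-hemizygous = chrX,
#' proband hemizygous-alt, mother het, father ref. Planted records are absent
#' from all population databases; background records carry database evidence
#' (presence flags, Hardy-Weinberg homozygote counts, floored at 1 where a
#' background record's genotype pattern would otherwise qualify under a
#' recessive model) so that at `genotype_error_rate = 0` no background record
#' survives [run_models()].
#'
#' @param config a [trio_sim_config()].
#' @return a list of class `trio_sim` with elements `records` (data frame),
#'   `truth` (data frame: `key`, `gene`, `model`, `pair_id`), `pedigree`
#'   (a [pedigree()]), and `config`.
#' @examples
#' sim <- simulate_trio(trio_sim_config(n_background_variants = 100, seed = 7))
#' table(sim$truth$model)
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  set.seed(config$seed)
  male <- config$proband_sex == "male"

  # Background gene map: symbols on chromosomes 1-22 and X (~4% on X).
  n_genes <- config$n_genes
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  n_x <- max(1L, as.integer(round(0.04 * n_genes)))
  gene_chrom <- c(sample(as.character(1:22), max(0L, n_genes - n_x),
                         replace = TRUE), rep("X", min(n_x, n_genes)))
  gene_start <- integer(n_genes)
  for (ch in unique(gene_chrom)) {
    on_ch <- which(gene_chrom == ch)
    gene_start[on_ch] <- 1000000L + (seq_along(on_ch) - 1L) * 100000L
  }

  n_bg <- config$n_background_variants
  bg <- NULL
  if (n_bg > 0L) {
    gidx <- sample.int(n_genes, n_bg, replace = TRUE)
    chrom <- gene_chrom[gidx]
    pos <- gene_start[gidx] + sample.int(99999L, n_bg, replace = TRUE)
    # Resolve the rare position collision deterministically.
    key <- paste(chrom, pos)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      pos[dup] <- gene_start[gidx[dup]] + sample.int(99999L, length(dup),
                                                    replace = TRUE)
      key <- paste(chrom, pos)
    }

    rare <- stats::runif(n_bg) < config$maf_rare_fraction
    maf <- ifelse(rare, stats::runif(n_bg, 1e-4, 0.009),
                  stats::runif(n_bg, 0.05, 0.5))

    effect <- sample(EFFECT_LEVELS, n_bg, replace = TRUE,
                     prob = c(0.10, 0.03, 0.02, 0.12, 0.55, 0.18))
    indel_len <- ifelse(effect == "coding_indel",
                        sample.int(60L, n_bg, replace = TRUE), 0L)

    alleles <- random_snv_alleles(n_bg)
    ref <- alleles$ref
    alt <- alleles$alt
    is_indel <- indel_len > 0L
    if (any(is_indel)) {
      ins <- vapply(indel_len[is_indel], function(k)
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
        character(1))
      alt[is_indel] <- paste0(ref[is_indel], ins)
    }

    on_x <- chrom == "X"
    gm_dos <- stats::rbinom(n_bg, 2L, maf)                    # mother, diploid
    gf_dos <- ifelse(on_x, stats::rbinom(n_bg, 1L, maf),      # father hemi on X
                     stats::rbinom(n_bg, 2L, maf))
    a_m <- transmit_allele(gm_dos)
    a_f <- ifelse(on_x, gf_dos, transmit_allele(gf_dos))

    gt_mother <- dosage_to_gt(gm_dos)
    gt_father <- ifelse(on_x, c("ref", "hemi_alt")[gf_dos + 1L],
                        dosage_to_gt(gf_dos))
    if (male) {
      # Son: X from mother only.
      gt_proband <- ifelse(on_x, c("ref", "hemi_alt")[a_m + 1L],
                           dosage_to_gt(a_m + a_f))
    } else {
      gt_proband <- dosage_to_gt(a_m + a_f)
    }

    # Database evidence: presence follows MAF > 0 (all background variants
    # are catalogued); homozygote counts at Hardy-Weinberg expectation.
    hom_evs <- stats::rbinom(n_bg, 6500L, maf^2)
    hom_exac <- stats::rbinom(n_bg, 60000L, maf^2)
    hemi_exac <- ifelse(on_x, stats::rbinom(n_bg, 30000L, maf), 0L)

    # Separability floor: any background record whose genotype pattern could
    # qualify under a recessive/X model keeps database evidence >= 1.
    hom_pattern <- !on_x & gt_proband == "hom_alt" &
      gt_mother == "het" & gt_father == "het"
    trans_pattern <- gt_proband == "het" &
      ((gt_mother %in% c("het", "hom_alt") & gt_father == "ref") |
         (gt_father %in% c("het", "hom_alt") & gt_mother == "ref"))
    x_pattern <- on_x & gt_proband == "hemi_alt" &
      gt_mother == "het" & gt_father == "ref"
    hom_exac[hom_pattern | trans_pattern] <-
      pmax(1L, hom_exac[hom_pattern | trans_pattern])
    hemi_exac[x_pattern] <- pmax(1L, hemi_exac[x_pattern])

    score_or_na <- function(x) ifelse(stats::runif(n_bg) < 0.2, NA_real_, x)
    bg <- new_trio_records(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      gene = genes[gidx], effect = effect, indel_len = indel_len,
      gt_proband = gt_proband, gt_mother = gt_mother, gt_father = gt_father,
      dbsnp_maf = maf,
      present_dbsnp = rep(TRUE, n_bg), present_1kg = rep(TRUE, n_bg),
      present_evs = rep(TRUE, n_bg), present_exac = rep(TRUE, n_bg),
      hom_count_evs = hom_evs, hom_count_exac = hom_exac,
      hemi_count_exac = hemi_exac,
      phylop = score_or_na(stats::runif(n_bg, -2, 8)),
      phastcons = score_or_na(stats::runif(n_bg)),
      gerp = score_or_na(stats::runif(n_bg, -3, 6)),
      cadd = score_or_na(stats::runif(n_bg, 0, 40)),
      polyphen2 = score_or_na(stats::runif(n_bg)),
      provean = score_or_na(stats::runif(n_bg, -8, 2)),
      sift = score_or_na(stats::runif(n_bg)),
      mutationtaster = score_or_na(stats::runif(n_bg)))
  }

  # Planted causal variants: dedicated genes, damaging scores, no database
  # evidence.
  plant_one <- function(gene, chrom, pos, gt_p, gt_m, gt_f) {
    al <- random_snv_alleles(1L)
    new_trio_records(
      chrom = chrom, pos = pos, ref = al$ref, alt = al$alt, gene = gene,
      effect = "nonsynonymous", indel_len = 0L,
      gt_proband = gt_p, gt_mother = gt_m, gt_father = gt_f,
      dbsnp_maf = NA_real_,
      present_dbsnp = FALSE, present_1kg = FALSE,
      present_evs = FALSE, present_exac = FALSE,
      hom_count_evs = 0L, hom_count_exac = 0L, hemi_count_exac = 0L,
      phylop = stats::runif(1, 3, 8), phastcons = stats::runif(1, 0.95, 1),
      gerp = stats::runif(1, 3, 6), cadd = stats::runif(1, 25, 40),
      polyphen2 = stats::runif(1, 0.9, 1), provean = stats::runif(1, -8, -4),
      sift = stats::runif(1, 0, 0.04),
      mutationtaster = stats::runif(1, 0.9, 1))
  }

  planted <- config$planted
  plant_rows <- list()
  truth_rows <- list()
  plant_pos <- 90000000L
  next_pos <- function() {
    plant_pos <<- plant_pos + 1000L
    plant_pos
  }
  add_truth <- function(rec, model, pair_id = NA_character_) {
    truth_rows[[length(truth_rows) + 1L]] <<-
      data.frame(key = variant_key(rec), gene = rec$gene, model = model,
                 pair_id = pair_id, stringsAsFactors = FALSE)
  }
  for (i in seq_len(planted[["de_novo"]])) {
    rec <- plant_one(sprintf("GENEDN%02d", i), sample(as.character(1:22), 1L),
                     next_pos(), "het", "ref", "ref")
    plant_rows[[length(plant_rows) + 1L]] <- rec
    add_truth(rec, "de_novo")
  }
  for (i in seq_len(planted[["hom_recessive"]])) {
    rec <- plant_one(sprintf("GENEHR%02d", i), sample(as.character(1:22), 1L),
                     next_pos(), "hom_alt", "het", "het")
    plant_rows[[length(plant_rows) + 1L]] <- rec
    add_truth(rec, "hom_recessive")
  }
  for (i in seq_len(planted[["comp_het"]] %/% 2L)) {
    g <- sprintf("GENECH%02d", i)
    ch <- sample(as.character(1:22), 1L)
    pair <- sprintf("CH%02d", i)
    rec1 <- plant_one(g, ch, next_pos(), "het", "het", "ref")  # maternal
    rec2 <- plant_one(g, ch, next_pos(), "het", "ref", "het")  # paternal
    plant_rows <- c(plant_rows, list(rec1, rec2))
    add_truth(rec1, "comp_het", pair)
    add_truth(rec2, "comp_het", pair)
  }
  for (i in seq_len(planted[["x_hemizygous"]])) {
    rec <- plant_one(sprintf("GENEXH%02d", i), "X", next_pos(),
                     "hemi_alt", "het", "ref")
    plant_rows[[length(plant_rows) + 1L]] <- rec
    add_truth(rec, "x_hemizygous")
  }

  records <- rbind(bg %||% new_trio_records(),
                   if (length(plant_rows)) do.call(rbind, plant_rows)
                   else new_trio_records())
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
  else data.frame(key = character(), gene = character(),
                  model = character(), pair_id = character(),
                  stringsAsFactors = FALSE)

  # Optional genotype noise on the proband call.
  e <- config$genotype_error_rate
  if (e > 0 && nrow(records) > 0) {
    hit <- which(stats::runif(nrow(records)) < e)
    for (i in hit) {
      valid <- if (is_sex_chrom(records$chrom[i]) && male)
        c("ref", "hemi_alt") else c("ref", "het", "hom_alt")
      alts <- setdiff(valid, records$gt_proband[i])
      records$gt_proband[i] <- sample(alts, 1L)
    }
  }

  records <- sort_records(records)
  rownames(records) <- NULL
  structure(list(records = records, truth = truth,
                 pedigree = pedigree(proband_sex = config$proband_sex),
                 config = config),
            class = "trio_sim")
}
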