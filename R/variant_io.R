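# Trio variant dataset I/O: VCF 4.2 + sidecar annotation TSV <-> the record
# model, and candidate-report serialization.

ANNOTATION_COLUMNS <- c("CHROM", "POS", "REF", "ALT", "GENE", "EFFECT",
                        "INDEL_LEN", "DBSNP_MAF", "PRESENT_DBSNP",
                        "PRESENT_1KG", "PRESENT_EVS", "PRESENT_EXAC",
                        "HOM_EVS", "HOM_EXAC", "HEMI_EXAC", "PHYLOP",
                        "PHASTCONS", "GERP", "CADD", "POLYPHEN2", "PROVEAN",
                        "SIFT", "MUTATIONTASTER")

#' Define the trio pedigree
#'
#' @param proband_id,mother_id,father_id sample labels; must match the VCF
#'   genotype column names.
#' @param proband_sex `"male"` or `"female"`; controls hemizygous genotype
#'   decoding on chrX/chrY and the X-hemizygous inheritance model.
#' @return a `pedigree` object.
#' @export
pedigree <- function(proband_id = "proband", mother_id = "mother",
                     father_id = "father",
                     proband_sex = c("male", "female")) {
  proband_sex <- match.arg(proband_sex)
  ids <- c(proband_id, mother_id, father_id)
  if (anyDuplicated(ids)) stop("pedigree sample labels must be distinct")
  structure(list(proband_id = proband_id, mother_id = mother_id,
                 father_id = father_id, proband_sex = proband_sex),
            class = "pedigree")
}

#' Write a trio VCF
#'
#' Emits a minimal VCF 4.2 with three genotype columns (proband, mother,
#' father, in pedigree order) and a GT-only FORMAT. Male genotypes on
#' chrX/chrY are written as single-allele calls (`0`/`1`). The seed is
#' recorded in a `##seed=` header line.
#'
#' @param records trio record data frame.
#' @param path output file path.
#' @param ped a [pedigree()].
#' @param seed integer seed recorded in the header (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(records, path, ped = pedigree(), seed = NULL) {
  records <- sort_records(records)
  male <- ped$proband_sex == "male"
  header <- c("##fileformat=VCFv4.2",
              provenance_lines(seed, prefix = "##"),
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     ped$proband_id, "\t", ped$mother_id, "\t", ped$father_id))
  body <- if (nrow(records)) {
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          "PASS", ".", "GT",
          encode_gt(records$gt_proband, records$chrom, male),
          encode_gt(records$gt_mother, records$chrom, FALSE),
          encode_gt(records$gt_father, records$chrom, TRUE),
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

format_number_col <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  out
}

#' Write the sidecar annotation table
#'
#' Tab-separated annotation keyed on (CHROM, POS, REF, ALT); empty string
#' means missing. Column set and order follow the pipeline's external
#' interface (see `ANNOTATION_COLUMNS`).
#'
#' @inheritParams write_trio_vcf
#' @return `path`, invisibly.
#' @export
write_trio_annotation <- function(records, path, seed = NULL) {
  records <- sort_records(records)
  tab <- data.frame(
    CHROM = records$chrom, POS = records$pos, REF = records$ref,
    ALT = records$alt, GENE = records$gene, EFFECT = records$effect,
    INDEL_LEN = records$indel_len,
    DBSNP_MAF = format_number_col(records$dbsnp_maf),
    PRESENT_DBSNP = records$present_dbsnp, PRESENT_1KG = records$present_1kg,
    PRESENT_EVS = records$present_evs, PRESENT_EXAC = records$present_exac,
    HOM_EVS = records$hom_count_evs, HOM_EXAC = records$hom_count_exac,
    HEMI_EXAC = records$hemi_count_exac,
    PHYLOP = format_number_col(records$phylop),
    PHASTCONS = format_number_col(records$phastcons),
    GERP = format_number_col(records$gerp),
    CADD = format_number_col(records$cadd),
    POLYPHEN2 = format_number_col(records$polyphen2),
    PROVEAN = format_number_col(records$provean),
    SIFT = format_number_col(records$sift),
    MUTATIONTASTER = format_number_col(records$mutationtaster),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a simulation truth table
#'
#' @param truth truth data frame from a generator.
#' @inheritParams write_trio_vcf
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a full simulated trio dataset
#'
#' Convenience wrapper writing `<stem>.vcf`, `<stem>_annotation.tsv` and
#' `<stem>_truth.tsv` for a [simulate_trio()] result.
#'
#' @param sim a `trio_sim` object.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the three paths, invisibly.
#' @export
write_trio <- function(sim, dir, stem = "trio") {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, paste0(stem, ".vcf")),
             annotation = file.path(dir, paste0(stem, "_annotation.tsv")),
             truth = file.path(dir, paste0(stem, "_truth.tsv")))
  seed <- sim$config$seed
  write_trio_vcf(sim$records, paths[["vcf"]], sim$pedigree, seed)
  write_trio_annotation(sim$records, paths[["annotation"]], seed)
  write_truth_table(sim$truth, paths[["truth"]], seed)
  invisible(paths)
}

parse_logical_col <- function(x) {
  x <- toupper(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' Read a trio variant dataset into the record model
#'
#' Parses a VCF (via \pkg{vcfR}) together with its sidecar annotation table.
#' Multiallelic rows are split into one record per ALT allele. Chromosome
#' labels are normalized by stripping a leading `"chr"`. Genotypes with any
#' missing allele map to `"missing"`; for a male proband, single-allele and
#' `1/1` calls on chrX/chrY both decode as hemizygous-alt.
#'
#' Annotation rows that match no VCF record are not silently dropped: their
#' count is attached as attribute `unmatched_annotation` and a warning is
#' raised. VCF records without an annotation row keep `NA` annotation fields
#' (attribute `unannotated`).
#'
#' @param vcf_path path to a VCF 4.x file containing the three pedigree
#'   samples.
#' @param annotation_path path to the annotation TSV (columns
#'   `ANNOTATION_COLUMNS`; empty string = missing).
#' @param ped a [pedigree()].
#' @return trio record data frame (see [new_trio_records()]).
#' @export
read_trio <- function(vcf_path, annotation_path, ped = pedigree()) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- v@gt
  fix <- v@fix
  n_rows <- nrow(fix)

  if (n_rows > 0) {
    samples <- colnames(gt)[-1]
    need <- c(ped$proband_id, ped$mother_id, ped$father_id)
    if (!all(need %in% samples))
      stop("VCF is missing pedigree sample(s): ",
           paste(setdiff(need, samples), collapse = ", "))
  }

  male <- ped$proband_sex == "male"
  rows <- vector("list", n_rows)
  for (i in seq_len(n_rows)) {
    chrom <- normalize_chrom(fix[i, "CHROM"])
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gt_p <- gt[i, ped$proband_id]
    gt_m <- gt[i, ped$mother_id]
    gt_f <- gt[i, ped$father_id]
    per_alt <- lapply(seq_along(alts), function(k) {
      new_trio_records(
        chrom = chrom, pos = pos, ref = ref, alt = alts[k],
        gene = NA_character_, effect = NA_character_, indel_len = NA_integer_,
        gt_proband = decode_gt(gt_p, k, chrom, male),
        gt_mother = decode_gt(gt_m, k, chrom, FALSE),
        gt_father = decode_gt(gt_f, k, chrom, TRUE),
        dbsnp_maf = NA_real_, present_dbsnp = NA, present_1kg = NA,
        present_evs = NA, present_exac = NA, hom_count_evs = NA_integer_,
        hom_count_exac = NA_integer_, hemi_count_exac = NA_integer_,
        phylop = NA_real_, phastcons = NA_real_, gerp = NA_real_,
        cadd = NA_real_, polyphen2 = NA_real_, provean = NA_real_,
        sift = NA_real_, mutationtaster = NA_real_)
    })
    rows[[i]] <- do.call(rbind, per_alt)
  }
  records <- if (n_rows) do.call(rbind, rows) else new_trio_records()

  anno <- utils::read.delim(annotation_path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(anno))
  if (length(missing_cols))
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  anno$CHROM <- normalize_chrom(anno$CHROM)
  anno_key <- paste(anno$CHROM, anno$POS, anno$REF, anno$ALT, sep = ":")
  if (anyDuplicated(anno_key))
    stop("annotation key collision on (CHROM, POS, REF, ALT): ",
         anno_key[duplicated(anno_key)][1])

  rec_key <- variant_key(records)
  hit <- match(rec_key, anno_key)
  matched <- !is.na(hit)
  num <- function(col) as.numeric(ifelse(anno[[col]] == "", NA, anno[[col]]))
  int <- function(col) as.integer(ifelse(anno[[col]] == "", NA, anno[[col]]))
  if (any(matched)) {
    j <- hit[matched]
    records$gene[matched] <- ifelse(anno$GENE[j] == "", NA, anno$GENE[j])
    records$effect[matched] <- ifelse(anno$EFFECT[j] == "", NA, anno$EFFECT[j])
    records$indel_len[matched] <- int("INDEL_LEN")[j]
    records$dbsnp_maf[matched] <- num("DBSNP_MAF")[j]
    records$present_dbsnp[matched] <- parse_logical_col(anno$PRESENT_DBSNP)[j]
    records$present_1kg[matched] <- parse_logical_col(anno$PRESENT_1KG)[j]
    records$present_evs[matched] <- parse_logical_col(anno$PRESENT_EVS)[j]
    records$present_exac[matched] <- parse_logical_col(anno$PRESENT_EXAC)[j]
    records$hom_count_evs[matched] <- int("HOM_EVS")[j]
    records$hom_count_exac[matched] <- int("HOM_EXAC")[j]
    records$hemi_count_exac[matched] <- int("HEMI_EXAC")[j]
    records$phylop[matched] <- num("PHYLOP")[j]
    records$phastcons[matched] <- num("PHASTCONS")[j]
    records$gerp[matched] <- num("GERP")[j]
    records$cadd[matched] <- num("CADD")[j]
    records$polyphen2[matched] <- num("POLYPHEN2")[j]
    records$provean[matched] <- num("PROVEAN")[j]
    records$sift[matched] <- num("SIFT")[j]
    records$mutationtaster[matched] <- num("MUTATIONTASTER")[j]
  }

  n_unmatched <- sum(!anno_key %in% rec_key)
  if (n_unmatched > 0)
    warning(n_unmatched, " annotation row(s) match no VCF record")
  attr(records, "unmatched_annotation") <- n_unmatched
  attr(records, "unannotated") <- sum(!matched)
  rownames(records) <- NULL
  records
}

#' Serialize a candidate report
#'
#' Writes the model calls as a TSV (one row per call; compound-het pairs
#' carry both member keys) plus a machine-readable funnel summary
#' (stage -> count) as a JSON sidecar at `<path>.funnel.json`. When a ranked
#' candidate table from [rank_candidates()] is supplied it is written next to
#' the report as `<path base>_ranked.tsv`.
#'
#' @param report a `candidate_report` from [run_models()].
#' @param path output TSV path.
#' @param ranked optional data frame from [rank_candidates()].
#' @param seed optional integer seed recorded in the header.
#' @return named vector of written paths, invisibly.
#' @export
write_candidate_report <- function(report, path, ranked = NULL, seed = NULL) {
  stopifnot(inherits(report, "candidate_report"))
  con <- file(path, "w")
  writeLines(provenance_lines(seed), con)
  utils::write.table(report$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  json_path <- paste0(path, ".funnel.json")
  jsonlite::write_json(as.list(report$funnel), json_path, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(report = path, funnel = json_path)
  if (!is.null(ranked)) {
    ranked_path <- sub("\\.tsv$", "", path)
    ranked_path <- paste0(ranked_path, "_ranked.tsv")
    con <- file(ranked_path, "w")
    writeLines(provenance_lines(seed), con)
    utils::write.table(ranked, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    close(con)
    paths <- c(paths, ranked = ranked_path)
  }
  invisible(paths)
}

#' Read back a funnel summary
#'
#' @param path path to a `.funnel.json` sidecar written by
#'   [write_candidate_report()].
#' @return named integer vector of stage counts, in file order.
#' @export
read_funnel_summary <- function(path) {
  x <- jsonlite::read_json(path)
  stats::setNames(vapply(x, function(v) as.integer(v), integer(1)), names(x))
}
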