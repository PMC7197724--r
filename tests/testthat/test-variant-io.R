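write_mini_vcf <- function(path, body,
                           samples = c("proband", "mother", "father")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(samples, collapse = "\t")),
               body), path)
}

write_mini_annotation <- function(path, rows) {
  header <- paste(c("CHROM", "POS", "REF", "ALT", "GENE", "EFFECT",
                    "INDEL_LEN", "DBSNP_MAF", "PRESENT_DBSNP", "PRESENT_1KG",
                    "PRESENT_EVS", "PRESENT_EXAC", "HOM_EVS", "HOM_EXAC",
                    "HEMI_EXAC", "PHYLOP", "PHASTCONS", "GERP", "CADD",
                    "POLYPHEN2", "PROVEAN", "SIFT", "MUTATIONTASTER"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
}

anno_line <- function(chrom, pos, ref, alt, gene = "G1",
                      effect = "nonsynonymous") {
  paste(chrom, pos, ref, alt, gene, effect, 0, 0.001, "TRUE", "FALSE",
        "FALSE", "FALSE", 0, 0, 0, 1.5, 0.5, 1, 10, 0.5, "-1", 0.5, 0.5,
        sep = "\t")
}

test_that("write -> read round trip reproduces the generator's records", {
  sim <- simulate_trio(trio_sim_config(n_background_variants = 250L,
                                       n_genes = 40L, seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_trio(sim, dir)
  rec <- read_trio(paths[["vcf"]], paths[["annotation"]], sim$pedigree)
  expect_equal(nrow(rec), nrow(sim$records))
  expect_equal(rec, sim$records, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(rec, "unmatched_annotation"), 0L)
})

test_that("genotype fields map onto the record model", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  anno <- file.path(dir, "t.tsv")
  write_mini_vcf(vcf, c("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
                        "X\t500\t.\tC\tT\t.\tPASS\t.\tGT\t1\t0/1\t0",
                        "2\t200\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0|1\t1/1"))
  write_mini_annotation(anno, c(anno_line("1", 100, "A", "G"),
                                anno_line("X", 500, "C", "T"),
                                anno_line("2", 200, "G", "A")))
  rec <- read_trio(vcf, anno, pedigree(proband_sex = "male"))
  r1 <- rec[rec$chrom == "1", ]
  expect_equal(c(r1$gt_proband, r1$gt_mother, r1$gt_father),
               c("het", "ref", "ref"))
  rx <- rec[rec$chrom == "X", ]
  expect_equal(c(rx$gt_proband, rx$gt_mother, rx$gt_father),
               c("hemi_alt", "het", "ref"))
  r2 <- rec[rec$chrom == "2", ]
  expect_equal(c(r2$gt_proband, r2$gt_mother, r2$gt_father),
               c("missing", "het", "hom_alt"))
})

test_that("male 1/1 on chrX decodes as hemizygous-alt", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  anno <- file.path(dir, "t.tsv")
  write_mini_vcf(vcf, "X\t500\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0")
  write_mini_annotation(anno, anno_line("X", 500, "C", "T"))
  rec <- read_trio(vcf, anno, pedigree(proband_sex = "male"))
  expect_equal(rec$gt_proband, "hemi_alt")
  rec <- read_trio(vcf, anno, pedigree(proband_sex = "female"))
  expect_equal(rec$gt_proband, "hom_alt")
})

test_that("multiallelic rows split into per-alt records", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  anno <- file.path(dir, "t.tsv")
  write_mini_vcf(vcf, "3\t300\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/1\t0/2")
  write_mini_annotation(anno, c(anno_line("3", 300, "A", "G"),
                                anno_line("3", 300, "A", "T", gene = "G2")))
  rec <- read_trio(vcf, anno, pedigree())
  expect_equal(nrow(rec), 2L)
  g <- rec[rec$alt == "G", ]
  expect_equal(c(g$gt_proband, g$gt_mother, g$gt_father),
               c("het", "het", "ref"))
  t_ <- rec[rec$alt == "T", ]
  expect_equal(c(t_$gt_proband, t_$gt_mother, t_$gt_father),
               c("het", "ref", "het"))
  expect_equal(t_$gene, "G2")
})

test_that("missing pedigree sample and annotation collisions are fatal; unmatched rows are reported", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  anno <- file.path(dir, "t.tsv")
  write_mini_vcf(vcf, "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
                 samples = c("proband", "mother", "uncle"))
  write_mini_annotation(anno, anno_line("1", 100, "A", "G"))
  expect_error(read_trio(vcf, anno, pedigree()), "father")

  write_mini_vcf(vcf, "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0")
  write_mini_annotation(anno, c(anno_line("1", 100, "A", "G"),
                                anno_line("1", 100, "A", "G", gene = "G9")))
  expect_error(read_trio(vcf, anno, pedigree()), "collision")

  write_mini_annotation(anno, c(anno_line("1", 100, "A", "G"),
                                anno_line("9", 999, "A", "G")))
  expect_warning(rec <- read_trio(vcf, anno, pedigree()), "match no VCF")
  expect_equal(attr(rec, "unmatched_annotation"), 1L)
})

test_that("funnel summary survives a write -> read round trip", {
  sim <- simulate_trio(trio_sim_config(n_background_variants = 150L,
                                       seed = 21))
  report <- run_models(sim$records, sim$pedigree)
  dir <- withr::local_tempdir()
  paths <- write_candidate_report(report, file.path(dir, "rep.tsv"),
                                  seed = 21)
  back <- read_funnel_summary(paths[["funnel"]])
  expect_identical(back, report$funnel)
})

test_that("an empty report writes a header-only table with zero counts", {
  report <- run_models(record_row()[0, ], pedigree())
  expect_true(all(report$funnel == 0L))
  dir <- withr::local_tempdir()
  paths <- write_candidate_report(report, file.path(dir, "rep.tsv"))
  lines <- readLines(paths[["report"]])
  expect_match(lines[length(lines)], "^model\t")
  expect_true(all(read_funnel_summary(paths[["funnel"]]) == 0L))
})
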