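test_that("de novo calls require proband het with both parents reference", {
  rec <- records_of(
    record_row(gene = "A", gt_proband = "het"),
    record_row(gene = "B", gt_proband = "het", gt_mother = "het"),
    record_row(gene = "C", gt_proband = "ref"),
    record_row(gene = "D", chrom = "X", gt_proband = "hemi_alt"))
  calls <- call_de_novo(rec)
  expect_setequal(calls$gene, c("A", "D"))  # chrX hemi de novo counts too
  expect_true(all(calls$model == "de_novo"))
})

test_that("homozygous-recessive calls require hom proband with two carrier parents", {
  rec <- records_of(
    record_row(gene = "A", gt_proband = "hom_alt", gt_mother = "het",
               gt_father = "het"),
    record_row(gene = "B", gt_proband = "hom_alt", gt_mother = "ref",
               gt_father = "het"),
    record_row(gene = "C", gt_proband = "het", gt_mother = "het",
               gt_father = "het"),
    record_row(gene = "D", chrom = "X", gt_proband = "hemi_alt",
               gt_mother = "het", gt_father = "ref"))
  calls <- call_homozygous(rec)
  expect_equal(calls$gene, "A")
})

test_that("compound-het pairing requires trans configuration", {
  mk <- function(gene, gm, gf, pos) {
    record_row(gene = gene, pos = pos, gt_proband = "het", gt_mother = gm,
               gt_father = gf)
  }
  # one maternal + one paternal -> one call
  rec <- rbind(mk("G", "het", "ref", 100L), mk("G", "ref", "het", 200L))
  calls <- call_compound_het(rec)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene, "G")
  # two maternal-only hets (cis) -> no call
  rec <- rbind(mk("G", "het", "ref", 100L), mk("G", "het", "ref", 200L))
  expect_equal(nrow(call_compound_het(rec)), 0L)
  # permissive mode pairs them anyway
  expect_equal(nrow(call_compound_het(rec, phase_mode = "permissive")), 1L)
  # 2 maternal + 1 paternal -> exactly 2 calls
  rec <- rbind(mk("G", "het", "ref", 100L), mk("G", "het", "ref", 200L),
               mk("G", "ref", "het", 300L))
  expect_equal(nrow(call_compound_het(rec)), 2L)
  # hom-alt transmitting parent still counts as trans
  rec <- rbind(mk("G", "hom_alt", "ref", 100L), mk("G", "ref", "het", 200L))
  expect_equal(nrow(call_compound_het(rec)), 1L)
  # different genes never pair
  rec <- rbind(mk("G1", "het", "ref", 100L), mk("G2", "ref", "het", 200L))
  expect_equal(nrow(call_compound_het(rec)), 0L)
})

test_that("X-hemizygous calls require a carrier mother and male proband", {
  rec <- records_of(
    record_row(gene = "A", chrom = "X", gt_proband = "hemi_alt",
               gt_mother = "het", gt_father = "ref"),
    record_row(gene = "B", chrom = "X", gt_proband = "hemi_alt",
               gt_mother = "ref", gt_father = "ref"),
    record_row(gene = "C", gt_proband = "hom_alt", gt_mother = "het",
               gt_father = "het"))
  calls <- call_x_hemizygous(rec, pedigree(proband_sex = "male"))
  expect_equal(calls$gene, "A")
  expect_message(
    calls_f <- call_x_hemizygous(rec, pedigree(proband_sex = "female")),
    "female")
  expect_equal(nrow(calls_f), 0L)
})

test_that("database exclusion follows the model-specific rules", {
  rec <- records_of(
    record_row(gene = "A", gt_proband = "het", present_dbsnp = TRUE),
    record_row(gene = "B", gt_proband = "hom_alt", gt_mother = "het",
               gt_father = "het", hom_count_exac = 3L),
    record_row(gene = "C", gt_proband = "hom_alt", gt_mother = "het",
               gt_father = "het", present_dbsnp = TRUE),
    record_row(gene = "D", chrom = "X", gt_proband = "hemi_alt",
               gt_mother = "het", gt_father = "ref", hemi_count_exac = 2L))
  calls <- apply_db_exclusion(rbind(call_de_novo(rec), call_homozygous(rec),
                                    call_x_hemizygous(rec)), rec)
  by_gene <- setNames(calls$excluded_by_db, calls$gene)
  expect_true(by_gene[["A"]])   # dominant: any database presence excludes
  expect_true(by_gene[["B"]])   # recessive: homozygotes in ExAC exclude
  expect_false(by_gene[["C"]])  # recessive keys on homozygotes, not presence
  expect_true(by_gene[["D"]])   # X model: hemizygotes exclude
  # comp-het pair excluded if either member carries homozygote evidence
  pair <- records_of(
    record_row(gene = "G", gt_proband = "het", gt_mother = "het",
               hom_count_evs = 1L),
    record_row(gene = "G", gt_proband = "het", gt_father = "het"))
  ch <- apply_db_exclusion(call_compound_het(pair), pair)
  expect_true(ch$excluded_by_db)
})

test_that("run_models recovers exactly the planted genes and empty input yields zero counts", {
  sim <- simulate_trio(trio_sim_config(n_background_variants = 2000L,
                                       seed = 31))
  report <- run_models(sim$records, sim$pedigree)
  expect_setequal(report$candidate_genes, unique(sim$truth$gene))
  expect_equal(report$funnel[["total"]], nrow(sim$records))
  expect_true(report$funnel[["functional"]] >= report$funnel[["rare"]])

  empty <- run_models(record_row()[0, ], pedigree())
  expect_true(all(empty$funnel == 0L))
  expect_length(empty$candidate_genes, 0L)
})

test_that("emitted calls always satisfy their model's genotype predicate", {
  for (seed in 1:10) {
    rec <- random_trio_records(80, seed = seed)
    report <- run_models(rec, pedigree())
    keys <- variant_key(report$records)
    for (r in seq_len(nrow(report$calls))) {
      call <- report$calls[r, ]
      v <- report$records[match(call$key, keys), ]
      switch(call$model,
        de_novo = {
          expect_true(v$gt_proband %in% c("het", "hemi_alt"))
          expect_equal(c(v$gt_mother, v$gt_father), c("ref", "ref"))
        },
        hom_recessive = {
          expect_equal(c(v$gt_proband, v$gt_mother, v$gt_father),
                       c("hom_alt", "het", "het"))
        },
        comp_het = {
          w <- report$records[match(call$key2, keys), ]
          expect_equal(c(v$gt_proband, w$gt_proband), c("het", "het"))
          expect_equal(v$gene, w$gene)
        },
        x_hemizygous = {
          expect_equal(v$chrom, "X")
          expect_equal(c(v$gt_proband, v$gt_mother, v$gt_father),
                       c("hemi_alt", "het", "ref"))
        })
    }
  }
})

test_that("adding database evidence never adds a candidate gene", {
  for (seed in 1:5) {
    rec <- random_trio_records(60, seed = seed)
    base <- run_models(rec, pedigree())$candidate_genes
    worse <- rec
    worse$present_dbsnp <- TRUE
    worse$hom_count_exac <- worse$hom_count_exac + 1L
    worse$hemi_count_exac <- ifelse(worse$chrom == "X",
                                    worse$hemi_count_exac + 1L,
                                    worse$hemi_count_exac)
    after <- run_models(worse, pedigree())$candidate_genes
    expect_true(all(after %in% base))
  }
})
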