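# Builders for trio records used across tests. Constructed as plain data
# frames (not via package internals) so tests stay independent of the
# implementation's constructors.

record_row <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       gene = "G1", effect = "nonsynonymous",
                       indel_len = 0L, gt_proband = "ref",
                       gt_mother = "ref", gt_father = "ref",
                       dbsnp_maf = NA_real_, present_dbsnp = FALSE,
                       present_1kg = FALSE, present_evs = FALSE,
                       present_exac = FALSE, hom_count_evs = 0L,
                       hom_count_exac = 0L, hemi_count_exac = 0L,
                       phylop = NA_real_, phastcons = NA_real_,
                       gerp = NA_real_, cadd = NA_real_,
                       polyphen2 = NA_real_, provean = NA_real_,
                       sift = NA_real_, mutationtaster = NA_real_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, effect = effect, indel_len = as.integer(indel_len),
             gt_proband = gt_proband, gt_mother = gt_mother,
             gt_father = gt_father, dbsnp_maf = dbsnp_maf,
             present_dbsnp = present_dbsnp, present_1kg = present_1kg,
             present_evs = present_evs, present_exac = present_exac,
             hom_count_evs = as.integer(hom_count_evs),
             hom_count_exac = as.integer(hom_count_exac),
             hemi_count_exac = as.integer(hemi_count_exac),
             phylop = phylop, phastcons = phastcons, gerp = gerp,
             cadd = cadd, polyphen2 = polyphen2, provean = provean,
             sift = sift, mutationtaster = mutationtaster,
             stringsAsFactors = FALSE)
}

records_of <- function(...) {
  out <- do.call(rbind, list(...))
  out$pos <- seq_len(nrow(out)) * 10L + out$pos  # keep keys unique
  out
}

# Random trio record tables exercising all genotype configurations, for the
# brute-force equivalence tests. All database fields are populated (no NAs)
# so predicate comparisons are exact.
random_trio_records <- function(n, seed) {
  set.seed(seed)
  n_genes <- max(3L, n %/% 4L)
  genes <- sprintf("R%03d", seq_len(n_genes))
  gene_chrom <- sample(c(as.character(1:22), "X"), n_genes, replace = TRUE,
                       prob = c(rep(1, 22), 6) / 28)
  gi <- sample.int(n_genes, n, replace = TRUE)
  chrom <- gene_chrom[gi]
  on_x <- chrom == "X"
  gt3 <- function(k) sample(c("ref", "het", "hom_alt", "missing"), k,
                            replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  gp <- ifelse(on_x, sample(c("ref", "hemi_alt", "missing"), n, replace = TRUE,
                            prob = c(0.4, 0.5, 0.1)), gt3(n))
  gm <- gt3(n)
  gf <- ifelse(on_x, sample(c("ref", "hemi_alt", "missing"), n, replace = TRUE,
                            prob = c(0.6, 0.3, 0.1)), gt3(n))
  effect <- sample(c("nonsynonymous", "coding_indel", "splice_site",
                     "synonymous", "intronic", "other"), n, replace = TRUE)
  indel_len <- ifelse(effect == "coding_indel",
                      sample(c(1:10, 45:55), n, replace = TRUE), 0L)
  maf <- ifelse(runif(n) < 0.4, NA_real_, runif(n, 0, 0.02))
  df <- record_row()[rep(1, n), ]
  df$chrom <- chrom
  df$pos <- sample.int(10000000L, n)
  df$ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  df$alt <- "T"
  df$gene <- genes[gi]
  df$effect <- effect
  df$indel_len <- as.integer(indel_len)
  df$gt_proband <- gp
  df$gt_mother <- gm
  df$gt_father <- gf
  df$dbsnp_maf <- maf
  df$present_dbsnp <- runif(n) < 0.3
  df$present_1kg <- runif(n) < 0.3
  df$present_evs <- runif(n) < 0.3
  df$present_exac <- runif(n) < 0.3
  df$hom_count_evs <- as.integer(rpois(n, 0.3))
  df$hom_count_exac <- as.integer(rpois(n, 0.3))
  df$hemi_count_exac <- ifelse(on_x, as.integer(rpois(n, 0.3)), 0L)
  rownames(df) <- NULL
  df
}
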