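# Shared internal helpers: variant keys, genotype codecs, seeded file headers.

GT_LEVELS <- c("ref", "het", "hom_alt", "hemi_alt", "missing")
EFFECT_LEVELS <- c("nonsynonymous", "coding_indel", "splice_site",
                   "synonymous", "intronic", "other")
MODEL_NAMES <- c("de_novo", "hom_recessive", "comp_het", "x_hemizygous")

#' Variant keys
#'
#' Canonical `chrom:pos:ref:alt` identifier used to join VCF rows with
#' annotation rows and to reference records from model calls.
#'
#' @param records a trio record data frame (see [read_trio()]).
#' @return character vector of keys, one per record.
#' @export
variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

is_sex_chrom <- function(chrom) chrom %in% c("X", "Y")

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Order chromosomes 1..22, X, Y, then anything else lexicographically.
chrom_rank <- function(chrom) {
  known <- c(as.character(1:22), "X", "Y")
  r <- match(chrom, known)
  r[is.na(r)] <- length(known) + 1L
  r
}

sort_records <- function(records) {
  records[order(chrom_rank(records$chrom), records$pos, records$ref,
                records$alt), , drop = FALSE]
}

# Encode an internal genotype label as a VCF GT string. Males are emitted
# with a single allele on chrX/chrY ("0"/"1"); everyone else diploid.
encode_gt <- function(gt, chrom, male) {
  hemi_zone <- is_sex_chrom(chrom) & male
  out <- character(length(gt))
  out[gt == "ref"] <- ifelse(hemi_zone[gt == "ref"], "0", "0/0")
  out[gt == "het"] <- "0/1"
  out[gt == "hom_alt"] <- "1/1"
  out[gt == "hemi_alt"] <- "1"
  out[gt == "missing"] <- ifelse(hemi_zone[gt == "missing"], ".", "./.")
  out
}

# Decode one VCF GT string against a given ALT allele index. Accepts "/" or
# "|" separators (phase ignored), single-allele calls, and for males on
# chrX/chrY also reads "k/k" as hemizygous-alt (both dialects occur in real
# callers). Any missing allele -> "missing".
decode_gt <- function(gt_string, alt_index, chrom, male) {
  if (is.na(gt_string) || gt_string == "" || gt_string == ".") return("missing")
  gt <- strsplit(gt_string, ":", fixed = TRUE)[[1]][1]
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) == 0) return("missing")
  suppressWarnings(al <- as.integer(alleles))
  if (any(is.na(al))) return("missing")
  n_alt <- sum(al == alt_index)
  hemi_zone <- is_sex_chrom(chrom) && male
  if (length(al) == 1L) {
    if (n_alt == 1L) return(if (hemi_zone) "hemi_alt" else "missing")
    return("ref")
  }
  if (n_alt == 2L) return(if (hemi_zone) "hemi_alt" else "hom_alt")
  if (n_alt == 1L) return("het")
  "ref"
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp a
# configuration fingerprint into output headers.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits only (byte values < 256); keep h as a double
    # because it exceeds R's 32-bit integer range.
    low <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    h <- (h %/% 65536) * 65536 + low
    # multiply mod 2^32 in 16-bit halves to stay within exact double range
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(unclass(config)), collapse = ""))
}

# Header comment lines stamped into every generated text table.
provenance_lines <- function(seed = NULL, extra = character(), prefix = "#") {
  lines <- c(sprintf("%s triofish version=%s", prefix,
                     as.character(utils::packageVersion("triofish"))))
  if (!is.null(seed)) lines <- c(lines, sprintf("%s seed=%d", prefix, as.integer(seed)))
  c(lines, extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
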