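# Small in-code fixtures shared across test files.

# 3-parent, 2-block, single-trait toy diallel written as raw records;
# pair (B,A) appears in non-canonical order on purpose.
toy_pheno_df <- function() {
  g <- data.frame(
    parent_a = c("A", "A", "A", "B", "B", "C"),
    parent_b = c("A", "B", "C", "B", "C", "C"),
    v1 = c(10, 12, 14, 11, 13, 16),
    v2 = c(11, 13, 13, 12, 14, 15)
  )
  out <- rbind(
    data.frame(parent_a = g$parent_a, parent_b = g$parent_b, block = 1,
      trait = "t", value = g$v1),
    data.frame(parent_a = g$parent_b, parent_b = g$parent_a, block = 2,
      trait = "t", value = g$v2)
  )
  out
}

toy_pheno <- function() as_diallel_pheno(toy_pheno_df(), c("A", "B", "C"))

# build a diallel_pheno directly from genotype-level values (one block)
pheno_from_genotypes <- function(parents, values_by_pair, trait = "t",
                                 blocks = 1) {
  rows <- do.call(rbind, lapply(seq_len(blocks), function(k) {
    data.frame(
      parent_a = values_by_pair$parent_a,
      parent_b = values_by_pair$parent_b,
      block = k, trait = trait, value = values_by_pair$value
    )
  }))
  as_diallel_pheno(rows, parents)
}

# hand-written toy VCF: 3 samples, 5 biallelic SNPs plus one indel and one
# multi-allelic record that readers must skip
toy_vcf_lines <- function() {
  c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t./.\t0/1",
    "chr1\t350\t.\tGA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "chr1\t375\t.\tT\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "chr2\t10\t.\tT\tC\t.\tPASS\t.\tGT\t0|1\t0/0\t0/0",
    "chr2\t20\t.\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t1/1"
  )
}

write_toy_vcf <- function() {
  path <- withr::local_tempfile(fileext = ".vcf",
    .local_envir = parent.frame())
  writeLines(toy_vcf_lines(), path)
  path
}

# expected dosages for the 5 retained SNP records of the toy VCF,
# hand-read from the GT fields above (rows samples, cols sites in order)
toy_vcf_dosages <- function() {
  rbind(
    S1 = c(0, 2, 0, 1, 2),
    S2 = c(1, 2, NA, 0, 0),
    S3 = c(2, 0, 1, 0, 2)
  )
}
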