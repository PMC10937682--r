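# formats_io: FASTA, GTF/CDS assembly, VCF with AD, expression TSV and
# the catalog TSV round trip.

test_that("read_fasta parses, uppercases and validates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.fa")

  writeLines(c(">t1", "ATGAAA"), p)
  expect_equal(read_fasta(p), c(t1 = "ATGAAA"))

  writeLines(c(">t1", "atg", "aaa"), p)
  expect_equal(read_fasta(p), c(t1 = "ATGAAA"))

  writeLines(c(">a", "ATG", ">a", "CCC"), p)
  expect_error(read_fasta(p), "duplicate.*'a'")

  writeLines(character(0), p)
  expect_error(read_fasta(p), "empty")

  writeLines(c(">t1", "ATG1AA"), p)
  expect_error(read_fasta(p), "non-IUPAC")
})

gtf_line <- function(chrom, feat, start, end, strand, tid = "T1", gid = "G1") {
  sprintf('%s\tsrc\t%s\t%d\t%d\t.\t%s\t0\tgene_id "%s"; transcript_id "%s";',
          chrom, feat, start, end, strand, gid, tid)
}

test_that("read_gtf_cds assembles CDS on both strands and splices exons", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "g.gtf")

  # single plus-strand exon (stop codon excluded by the annotation)
  writeLines(c(">c1", "ATGAAATGA"), fa)
  writeLines(gtf_line("c1", "CDS", 1, 6, "+"), gtf)
  txs <- read_gtf_cds(gtf, fa)
  expect_equal(txs$T1$cds_seq, "ATGAAA")
  expect_equal(txs$T1$strand, "+")

  # minus strand: CDS [4,9] over NNNTTTCAT reverse-complements to ATGAAA
  writeLines(c(">c1", "NNNTTTCAT"), fa)
  writeLines(gtf_line("c1", "CDS", 4, 9, "-"), gtf)
  txs <- read_gtf_cds(gtf, fa)
  expect_equal(txs$T1$cds_seq, "ATGAAA")

  # two exons spliced by concatenation
  writeLines(c(">c1", "ATGNNNAAA"), fa)
  writeLines(c(gtf_line("c1", "CDS", 1, 3, "+"),
               gtf_line("c1", "CDS", 7, 9, "+")), gtf)
  txs <- read_gtf_cds(gtf, fa)
  expect_equal(txs$T1$cds_seq, "ATGAAA")
  expect_equal(unname(txs$T1$cds_intervals[, "start"]), c(1, 7))

  # three_prime_utr is captured in transcript orientation
  writeLines(c(">c1", "ATGAAACCGGTT"), fa)
  writeLines(c(gtf_line("c1", "CDS", 1, 6, "+"),
               gtf_line("c1", "three_prime_utr", 7, 12, "+")), gtf)
  expect_equal(read_gtf_cds(gtf, fa)$T1$utr3_seq, "CCGGTT")
})

test_that("read_gtf_cds skips invalid transcripts with a warning, errors in strict mode", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "g.gtf")
  writeLines(c(">c1", "CTGAAATGAATGAAA"), fa)
  writeLines(c(gtf_line("c1", "CDS", 1, 6, "+", tid = "BAD"),
               gtf_line("c1", "CDS", 10, 15, "+", tid = "OK")), gtf)
  expect_warning(txs <- read_gtf_cds(gtf, fa), "skipping transcript BAD")
  expect_named(txs, "OK")
  expect_error(suppressWarnings(read_gtf_cds(gtf, fa, strict = TRUE)),
               "ATG")

  # interval outside the contig is always an error for that transcript
  writeLines(gtf_line("c1", "CDS", 1, 99, "+"), gtf)
  expect_error(read_gtf_cds(gtf, fa, strict = TRUE), "bounds")
})

test_that("read_vcf maps records, infers vclass and rejects multi-allelics", {
  p <- write_test_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:10,7",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT:AD\t0/1:12,4",
    "chr1\t300\t.\tG\tGCC\t.\tPASS\t.\tGT:AD\t0/1:9,6"))
  v <- read_vcf(p, "S")
  expect_equal(v$pos, c(100L, 200L, 300L))
  expect_equal(v$vclass, c("SNV", "deletion", "insertion"))
  expect_equal(v$alt_reads, c(7L, 4L, 6L))
  expect_equal(v$ref[1], "A")

  expect_error(read_vcf(p, "NOPE"), "sample 'NOPE'")

  p2 <- write_test_vcf("chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT:AD\t0/1:10,7,2",
                       name = "multi.vcf")
  expect_error(read_vcf(p2, "S"), "multi-allelic")

  p3 <- write_test_vcf("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
                       name = "noad.vcf")
  expect_error(read_vcf(p3, "S"), "AD")
})

test_that("readers accept gzip-compressed files", {
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "z.fa.gz")
  con <- gzfile(fp, "w"); writeLines(c(">t1", "ATGAAA"), con); close(con)
  expect_equal(read_fasta(fp), c(t1 = "ATGAAA"))

  ep <- file.path(dir, "e.tsv.gz")
  con <- gzfile(ep, "w")
  writeLines(c("gene_id\tTPM\tFPKM", "G1\t12.5\t10"), con); close(con)
  expect_equal(read_expression(ep), c(G1 = 12.5))
})

test_that("expression reader validates its contract", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "e.tsv")
  writeLines(c("gene_id\tTPM", "G1\t1.5", "G2\t0"), p)
  expect_equal(read_expression(p), c(G1 = 1.5, G2 = 0))
  writeLines(c("gene\tvalue", "G1\t1.5"), p)
  expect_error(read_expression(p), "gene_id and TPM")
  writeLines(c("gene_id\tTPM", "G1\t1.5", "G1\t2"), p)
  expect_error(read_expression(p), "duplicate")
  writeLines(c("gene_id\tTPM", "G1\t-2"), p)
  expect_error(read_expression(p), "non-negative")
})

test_that("catalog writes deterministically and round-trips", {
  dir <- withr::local_tempdir()
  rec <- data.frame(
    peptide = c("AAAAFAAL", "AAAAFAAL", "CCCCNCCM"),
    length = 8L, allele = c("H2-Kb", "H2-Db", "H2-Db"),
    percent_rank = c(0.1, 0.3, 0.1), ic50_nm = c(50, 120.5, 50),
    gene_id = c("G2", "G2", "G1"), transcript_id = c("T2", "T2", "T1"),
    variant = c("c1:5:A:T", "c1:5:A:T", "c2:9:G:C"), vclass = "SNV",
    tpm = c(12.5, 12.5, 0.125), wes_alt_reads = 10L, rna_alt_reads = 4L,
    class = c("shared", "shared", "unique_B"), stringsAsFactors = FALSE)
  p1 <- file.path(dir, "c1.tsv"); p2 <- file.path(dir, "c2.tsv")
  write_catalog(rec, p1)
  write_catalog(rec[c(3, 1, 2), ], p2)  # order-insensitive determinism
  expect_identical(readLines(p1), readLines(p2))

  back <- read_catalog(p1)
  expect_equal(nrow(back), 3L)
  # sorted by (gene_id, variant, peptide, allele)
  expect_equal(back$gene_id, c("G1", "G2", "G2"))
  ord <- order(rec$gene_id, rec$variant, rec$peptide, rec$allele)
  want <- rec[ord, neoforge:::CATALOG_COLUMNS]
  rownames(want) <- NULL
  expect_equal(back, want)

  # empty catalog -> header-only file
  p3 <- file.path(dir, "c3.tsv")
  write_catalog(rec[0, ], p3)
  expect_equal(readLines(p3),
               paste(neoforge:::CATALOG_COLUMNS, collapse = "\t"))
  expect_equal(nrow(read_catalog(p3)), 0L)
})

test_that("generated VCF alt_reads survive the writer/reader round trip", {
  dir <- withr::local_tempdir()
  txs <- generate_transcriptome(7, n_genes = 6)
  pv <- plant_variants(8, txs, n_missense = 3, n_synonymous = 1,
                       n_frameshift = 1, n_germline = 2, out_dir = dir)
  v <- read_vcf(file.path(dir, "tumor_a.vcf"), "TUMOR_A")
  expect_equal(sum(v$alt_reads), sum(pv$tumor_a$alt_reads))
  expect_setequal(neoforge:::variant_key(v),
                  neoforge:::variant_key(pv$tumor_a))
})
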