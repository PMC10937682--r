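# synthetic_data: validity of generated artifacts, recorded ground
# truth, determinism, and the statistical structure of the simulated
# cohort.

test_that("generated transcriptomes satisfy every CDS invariant", {
  dir <- withr::local_tempdir()
  txs <- generate_transcriptome(3, n_genes = 10, out_dir = dir)
  expect_length(txs$txs, 10L)

  # files parse in strict mode and reproduce the in-memory models
  parsed <- read_gtf_cds(file.path(dir, "annot.gtf"),
                         file.path(dir, "ref.fa"), strict = TRUE)
  expect_length(parsed, 10L)
  for (tid in names(txs$txs)) {
    expect_equal(parsed[[tid]]$cds_seq, txs$txs[[tid]]$cds_seq)
    expect_equal(parsed[[tid]]$utr3_seq, txs$txs[[tid]]$utr3_seq)
    expect_equal(parsed[[tid]]$strand, txs$txs[[tid]]$strand)
    # every CDS translates cleanly with no internal stop
    aa <- translate_cds(txs$txs[[tid]]$cds_seq)
    expect_equal(nchar(aa), nchar(txs$txs[[tid]]$cds_seq) / 3)
  }
  # both strands represented
  expect_setequal(unique(vapply(txs$txs, `[[`, character(1), "strand")),
                  c("+", "-"))
})

test_that("generators are byte-deterministic in their seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    txs <- generate_transcriptome(9, n_genes = 6, out_dir = d)
    pv <- plant_variants(10, txs, n_missense = 2, n_synonymous = 1,
                         n_frameshift = 1, n_germline = 2, out_dir = d)
    simulate_rna_support(11, pv, txs, out_dir = d)
    simulate_cohort(12, n = 120, out_path = file.path(d, "cohort.tsv"))
  }
  for (f in c("ref.fa", "annot.gtf", "tumor_a.vcf", "tumor_b.vcf",
              "normal.vcf", "rna_a.vcf", "rna_b.vcf", "expression.tsv",
              "cohort.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted variants honour the design contracts", {
  txs <- generate_transcriptome(21, n_genes = 8)
  pv <- plant_variants(22, txs, n_missense = 3, n_synonymous = 2,
                       n_frameshift = 2, n_germline = 3,
                       shared_fraction = 0.5)
  pl <- pv$truth$planted

  # exactly 3 germline variants present in tumour AND normal call sets
  germ_keys <- neoforge:::variant_key(pl[pl$germline, ])
  expect_length(germ_keys, 3L)
  expect_true(all(germ_keys %in% neoforge:::variant_key(pv$normal)))
  expect_true(all(germ_keys %in% neoforge:::variant_key(pv$tumor_a)))
  expect_true(all(germ_keys %in% neoforge:::variant_key(pv$tumor_b)))

  # line B is a strict superset of line A's somatic variants
  som_a <- neoforge:::variant_key(pl[pl$in_a & !pl$germline, ])
  som_b <- neoforge:::variant_key(pl[pl$in_b & !pl$germline, ])
  expect_true(all(som_a %in% som_b))
  expect_gt(length(som_b), length(som_a))

  # synonymous variants contribute zero expected peptides
  syn_keys <- neoforge:::variant_key(pl[pl$kind == "synonymous", ])
  expect_false(any(pv$truth$expected_peptides$variant %in% syn_keys))

  # the VCF ref alleles match the reference contigs
  for (i in seq_len(nrow(pl))) {
    expect_equal(substr(txs$fasta[[pl$chrom[i]]], pl$pos[i],
                        pl$pos[i] + nchar(pl$ref[i]) - 1L), pl$ref[i])
  }
})

test_that("forced-low read counts fall on the failing side of both filters", {
  txs <- generate_transcriptome(31, n_genes = 8)
  pv <- plant_variants(32, txs, n_missense = 6, n_synonymous = 0,
                       n_frameshift = 0, n_germline = 0, frac_low_wes = 0.5)
  pl <- pv$truth$planted
  expect_equal(sum(pl$forced_low_wes), 3L)
  expect_true(all(pl$wes_alt_a[pl$forced_low_wes] < 5))
  expect_true(all(pl$wes_alt_a[!pl$forced_low_wes] >= 5))

  rs <- simulate_rna_support(33, pv, txs, expressed_fraction = 1,
                             frac_low_rna = 0.5)
  expect_true(all(rs$rna_a$alt_reads[rs$forced_low_rna[match(
    neoforge:::variant_key(rs$rna_a), neoforge:::variant_key(pl))]] < 3))
})

test_that("unexpressed genes yield TPM 0 and vanish from RNA call sets", {
  txs <- generate_transcriptome(41, n_genes = 10)
  pv <- plant_variants(42, txs, n_missense = 5, n_synonymous = 0,
                       n_frameshift = 0, n_germline = 0)
  rs <- simulate_rna_support(43, pv, txs, expressed_fraction = 0.5)
  expect_true(all(rs$expression >= 0))
  expect_true(all(is.finite(rs$expression)))
  off <- setdiff(names(rs$expression), rs$expressed_genes)
  expect_true(all(rs$expression[off] == 0))
  pl <- pv$truth$planted
  unexpressed <- neoforge:::variant_key(pl[!pl$gene_id %in% rs$expressed_genes, ])
  expect_false(any(unexpressed %in% neoforge:::variant_key(rs$rna_b)))

  # expressed_fraction = 1: every line-B variant appears in rna_b
  rs2 <- simulate_rna_support(44, pv, txs, expressed_fraction = 1)
  expect_setequal(neoforge:::variant_key(rs2$rna_b),
                  neoforge:::variant_key(pl[pl$in_b | pl$germline, ]))
})

test_that("simulated cohorts have standardized genes and the planted coupling", {
  sim <- simulate_cohort(51, n = 400, beta = 1, hr = 2)
  ch <- sim$cohort
  genes <- setdiff(names(ch), c("sample_id", "tmb", "time_months", "event"))
  for (g in genes) {
    expect_equal(mean(ch[[g]]), 0, tolerance = 1e-6)
    expect_equal(sd(ch[[g]]), 1, tolerance = 1e-6)
  }
  expect_true(all(ch$time_months > 0))
  expect_true(all(ch$event %in% 0:1))

  # beta = 0: null coupling bound at large n
  sim0 <- simulate_cohort(52, n = 10000, beta = 0, hr = 1)
  z0 <- as.matrix(sim0$cohort[, genes])
  r0 <- pearson_r(signature_score(z0, signature_def("cdc1")),
                  signature_score(z0, signature_def("cd8_effector")))
  expect_lt(abs(r0$r), 3 / sqrt(10000))

  # written cohort round-trips through read_cohort
  p <- file.path(withr::local_tempdir(), "cohort.tsv")
  simulate_cohort(53, n = 150, out_path = p)
  back <- read_cohort(p)
  expect_equal(nrow(back), 150L)
  expect_true(all(genes %in% names(back)))
})
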