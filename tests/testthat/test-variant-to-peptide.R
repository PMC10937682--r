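# variant_to_peptide: translation, codon-aware variant application
# (including frameshift read-through), and 8-11-mer window enumeration
# with wild-type subtraction.

test_that("translate_cds follows the standard code, trailing-codon and stop rules", {
  expect_equal(translate_cds("ATGAAATGA"), "MK")
  expect_equal(translate_cds("ATGAAAA"), "MK")      # trailing base ignored
  expect_equal(translate_cds("TAAATGAAA"), "")      # immediate stop
  expect_error(translate_cds("ATGANA"), "untranslatable")
  expect_error(translate_cds(""), "non-empty")
})

test_that("apply_variant handles SNV consequences", {
  # MAFKGPQRST protein; codon 2 GCT
  cds <- paste0("ATG", "GCT", "TTT", "AAA", "GGG", "CCA", "CAA", "AGA",
                "TCA", "ACA")
  fx <- make_tx(cds)

  # missense: CDS nt 4 G->A turns GCT (A) into ACT (T)
  mp <- apply_variant(fx$tx, svar_at_cds(fx$tx, 4L, "A"))
  expect_equal(mp$wt_aa, "MAFKGPQRST")
  expect_equal(mp$mut_aa, "MTFKGPQRST")
  expect_equal(mp$mut_span, c(2L, 2L))
  expect_equal(mp$consequence, "missense")

  # synonymous: GCT -> GCA, empty span
  mp <- apply_variant(fx$tx, svar_at_cds(fx$tx, 6L, "A"))
  expect_null(mp$mut_span)
  expect_equal(mp$consequence, "synonymous")

  # stop gain: CAA -> TAA at codon 7 truncates with empty span
  mp <- apply_variant(fx$tx, svar_at_cds(fx$tx, 19L, "T"))
  expect_equal(mp$mut_aa, "MAFKGP")
  expect_null(mp$mut_span)
  expect_equal(mp$consequence, "stop_gain")
})

test_that("frameshift reads through into the 3' UTR until the next stop", {
  # wt MD; deleting the T of codon 2 (GAT) shifts into the UTR:
  # ATGGA + CATTTAAGG -> ATG GAC ATT TAA -> MDI
  fx <- make_tx("ATGGAT", utr3 = "CATTTAAGG")
  v <- svar(fx$tx$chrom, neoforge:::cds_to_genomic(fx$tx, 5L), "AT", "A")
  mp <- apply_variant(fx$tx, v)
  expect_equal(mp$wt_aa, "MD")
  expect_equal(mp$mut_aa, "MDI")
  expect_equal(mp$mut_span, c(2L, 3L))   # from the codon holding the edit
  expect_equal(mp$consequence, "frameshift")

  # no stop anywhere downstream -> translated to the end, with a warning
  fx2 <- make_tx("ATGGAT", utr3 = "CACCCACC")
  v2 <- svar(fx2$tx$chrom, neoforge:::cds_to_genomic(fx2$tx, 5L), "AT", "A")
  expect_warning(mp2 <- apply_variant(fx2$tx, v2), "without a stop")
  expect_equal(mp2$mut_aa, "MDTH")   # ATG GAC ACC CAC, trailing C ignored
})

test_that("apply_variant validates position and ref allele", {
  fx <- make_tx("ATGGCTTTTAAAGGGCCA", utr3 = "TAAATAAATAA")
  # outside the CDS -> NULL, not an error
  expect_null(apply_variant(fx$tx, svar(fx$tx$chrom, 1L, "C", "A")))
  # ref mismatch
  v <- svar_at_cds(fx$tx, 4L, "A"); v$ref <- "T"
  expect_error(apply_variant(fx$tx, v), "ref allele mismatch")
  # deletion running over the CDS edge
  gend <- neoforge:::cds_to_genomic(fx$tx, 18L)
  expect_error(
    apply_variant(fx$tx, svar(fx$tx$chrom, gend, "ACCCC", "A")),
    "spans a CDS boundary")
})

test_that("minus-strand application equals the plus-strand construction", {
  cds <- paste0("ATG", "GCT", "TTT", "AAA", "GGG", "CCA", "CAA", "AGA",
                "TCA", "ACA", "GAA", "GAC")
  utr <- "GGCCTTAAATAAATAA"
  for (cds_pos in c(4L, 8L, 15L)) {
    plus <- make_tx(cds, utr, strand = "+")
    minus <- make_tx(cds, utr, strand = "-")
    alt <- if (substr(cds, cds_pos, cds_pos) == "C") "G" else "C"
    mp_p <- apply_variant(plus$tx, svar_at_cds(plus$tx, cds_pos, alt))
    mp_m <- apply_variant(minus$tx, svar_at_cds(minus$tx, cds_pos, alt))
    expect_equal(mp_p$mut_aa, mp_m$mut_aa)
    expect_equal(mp_p$mut_span, mp_m$mut_span)
    expect_equal(enumerate_neoepitopes(mp_p)$sequence,
                 enumerate_neoepitopes(mp_m)$sequence)
  }
})

test_that("spliced (two-exon) transcripts assemble and mutate correctly", {
  cds <- paste0("ATG", "GCT", "TTT", "AAA", "GGG", "CCA", "CAA", "AGA",
                "TCA", "ACA")
  fx <- make_tx(cds, exon_break = 12L)
  mp <- apply_variant(fx$tx, svar_at_cds(fx$tx, 16L, "A"))  # codon 6 CCA -> ACA
  expect_equal(mp$consequence, "missense")
  expect_equal(mp$mut_span, c(6L, 6L))
})

test_that("window enumeration matches the closed forms and clips at termini", {
  wt <- REPEATFREE_40
  # interior missense at residue 15: 38 windows (8+9+10+11)
  mut <- wt
  substr(mut, 15, 15) <- "W"  # L -> W at position 15
  mp <- fake_mutant(wt, mut, c(15L, 15L))
  peps <- enumerate_neoepitopes(mp)
  expect_equal(nrow(peps), 38L)
  expect_equal(sum(peps$length == 8), 8L)
  expect_equal(sum(peps$length == 11), 11L)
  # ordered by (length, window_start), all contain the mutated residue
  expect_equal(peps$window_start, unlist(lapply(8:11, function(L)
    max(1, 15 - L + 1):min(40 - L + 1, 15))))
  expect_true(all(peps$window_start <= 15 &
                    peps$window_start + peps$length - 1 >= 15))

  # N-terminal clipping: missense at residue 2 -> 2 windows per length
  mut2 <- wt
  substr(mut2, 2, 2) <- "W"
  peps2 <- enumerate_neoepitopes(fake_mutant(wt, mut2, c(2L, 2L)))
  expect_equal(nrow(peps2), 8L)
  expect_equal(as.vector(table(peps2$length)), rep(2L, 4))

  # synonymous (empty span) -> no peptides
  expect_equal(nrow(enumerate_neoepitopes(fake_mutant(wt, wt, NULL))), 0L)
})

test_that("wild-type subtraction removes windows present in wt and dedups", {
  # mutant equal to wt except an appended novel tail: windows fully in
  # the wt prefix are subtracted
  wt <- REPEATFREE_40
  mut <- paste0(substr(wt, 1, 20), "WWWWWWWWWWWW")
  mp <- fake_mutant(wt, mut, c(21L, 32L))
  peps <- enumerate_neoepitopes(mp)
  expect_true(all(!vapply(peps$sequence, grepl, logical(1), x = wt,
                          fixed = TRUE)))
  expect_false(anyDuplicated(peps$sequence) > 0)
  # every peptide overlaps the mutated span
  expect_true(all(peps$window_start + peps$length - 1 >= 21))

  # widened subtraction: a proteome containing the mutant removes everything
  expect_equal(nrow(enumerate_neoepitopes(mp, wt_extra = mut)), 0L)
})

test_that("implementation agrees with the naive oracle on random planted variants", {
  # >= 100 random variants of all consequence classes across seeds
  n_checked <- 0L
  for (seed in 1:15) {
    txs <- generate_transcriptome(seed, n_genes = 6)
    pv <- plant_variants(seed + 500L, txs, n_missense = 3, n_synonymous = 1,
                         n_frameshift = 2, n_inframe = 2, n_germline = 0)
    pl <- pv$truth$planted
    for (i in seq_len(nrow(pl))) {
      r <- pl[i, ]
      tx <- txs$txs[[r$transcript_id]]
      mp <- apply_variant(tx, svar(r$chrom, r$pos, r$ref, r$alt))
      got <- sort(unique(enumerate_neoepitopes(mp)$sequence))
      key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
      want <- sort(unique(pv$truth$expected_peptides$sequence[
        pv$truth$expected_peptides$variant == key]))
      expect_identical(got, want,
                       label = sprintf("seed %d %s (%s)", seed, key, r$kind))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})
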