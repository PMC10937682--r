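# Fixture builders shared across test files. Everything is constructed
# in code; no binary fixtures exist anywhere in the package.

options(neoforge.verbose = FALSE)

# Build a single-exon (or two-exon) transcript model plus the contig it
# lives on, laid out as pad | CDS [| intron | CDS] | utr3 | pad. For
# strand == "-", the contig is reverse-complemented and coordinates are
# flipped, so the transcript-space content is identical to the plus
# construction.
make_tx <- function(cds, utr3 = "", strand = "+", chrom = "chrT",
                    tid = "TX1", gid = "G1", pad = 5L, exon_break = NULL) {
  layout <- paste0(strrep("C", pad), cds, utr3, strrep("C", pad))
  if (!is.null(exon_break)) {
    intron <- strrep("G", 9L)
    layout <- paste0(strrep("C", pad), substr(cds, 1, exon_break), intron,
                     substr(cds, exon_break + 1L, nchar(cds)), utr3,
                     strrep("C", pad))
    exons <- rbind(c(pad + 1L, pad + exon_break),
                   c(pad + exon_break + 10L, pad + nchar(cds) + 9L))
  } else {
    exons <- rbind(c(pad + 1L, pad + nchar(cds)))
  }
  lc <- nchar(layout)
  if (strand == "-") {
    contig <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(layout)))
    exons <- t(apply(exons, 1L, function(iv) c(lc - iv[2] + 1L, lc - iv[1] + 1L)))
    exons <- exons[order(-exons[, 1]), , drop = FALSE]  # transcript order
  } else {
    contig <- layout
  }
  tx <- structure(
    list(transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
         cds_intervals = cbind(start = exons[, 1], end = exons[, 2]),
         cds_seq = cds, utr3_seq = utr3),
    class = "transcript_model")
  list(tx = tx, fasta = setNames(contig, chrom))
}

# One-row somatic variant data frame; vclass inferred from the alleles.
svar <- function(chrom, pos, ref, alt, alt_reads = 10L, sample = "S") {
  vclass <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = vclass, alt_reads = as.integer(alt_reads),
             sample = sample, stringsAsFactors = FALSE)
}

# SNV positioned by CDS coordinate: converts to genomic for the given
# transcript and orients alleles by strand.
svar_at_cds <- function(tx, cds_pos, alt_base, ...) {
  gpos <- neoforge:::cds_to_genomic(tx, cds_pos)
  ref_t <- substr(tx$cds_seq, cds_pos, cds_pos)
  if (tx$strand == "+") {
    svar(tx$chrom, gpos, ref_t, alt_base, ...)
  } else {
    svar(tx$chrom, gpos, neoforge:::revcomp(ref_t),
         neoforge:::revcomp(alt_base), ...)
  }
}

# Minimal single-sample VCF text file; returns its path.
write_test_vcf <- function(rows, sample = "S",
                           name = "test.vcf",
                           path = tempfile(pattern = sub("\\.vcf$", "", name),
                                           fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

# A repeat-free 40-residue protein (no 8-mer occurs twice) used for
# window-count tests, plus a mutant_protein constructor for direct
# enumeration tests.
REPEATFREE_40 <- paste0("MACDEFGHIKLNPQRSTVWY", "MYWVTSRQPNLKIHGFEDCA")

fake_mutant <- function(wt_aa, mut_aa, span, vclass = "SNV") {
  structure(
    list(transcript_id = "TX1", gene_id = "G1", wt_aa = wt_aa,
         mut_aa = mut_aa, mut_span = span, consequence = "missense",
         variant = svar("chrT", 1L, "A", "T")),
    class = "mutant_protein")
}

# Full synthetic input directory (files on disk) for pipeline tests.
make_pipeline_dir <- function(seed, dir, aa_alphabet = "full",
                              n_genes = 10, expressed_fraction = 1,
                              strong_design = NULL, ...) {
  txs <- generate_transcriptome(seed, n_genes = n_genes,
                                aa_alphabet = aa_alphabet, out_dir = dir)
  pv <- plant_variants(seed + 1L, txs, strong_design = strong_design,
                       out_dir = dir, ...)
  rs <- simulate_rna_support(seed + 2L, pv, txs,
                             expressed_fraction = expressed_fraction,
                             out_dir = dir)
  list(txs = txs, pv = pv, rs = rs)
}

pipeline_cfg_for <- function(dir, out_dir = file.path(dir, "out"), ...) {
  pipeline_config(
    fasta = file.path(dir, "ref.fa"), gtf = file.path(dir, "annot.gtf"),
    wes_a = file.path(dir, "tumor_a.vcf"), wes_b = file.path(dir, "tumor_b.vcf"),
    normal = file.path(dir, "normal.vcf"),
    rna_a = file.path(dir, "rna_a.vcf"), rna_b = file.path(dir, "rna_b.vcf"),
    expression = file.path(dir, "expression.tsv"), out_dir = out_dir, ...)
}
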