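# Readers and writers for the standard formats the pipeline touches:
# FASTA, GTF (CDS features), VCF v4.x with AD, RSEM-style expression TSV,
# cohort TSV and the final catalog TSV. Coordinates are 1-based inclusive
# throughout, matching both the VCF and GTF standards.

#' Read a FASTA file into a named vector of uppercase sequences
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param kind `"dna"` or `"aa"`; controls alphabet validation.
#' @return Named character vector, one element per record, in file order.
#'   Sequences are uppercased; names are the full header lines minus `>`
#'   up to the first whitespace.
#' @details Duplicate ids, empty files and non-IUPAC characters are
#'   errors.
#' @export
read_fasta <- function(path, kind = c("dna", "aa")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stopf("FASTA record with empty id in %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate FASTA id '%s' in %s", dup[1], path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stopf("empty sequence for id '%s'", ids[which(!nzchar(seqs))[1]])
  }
  alphabet <- if (kind == "dna") "ACGTRYSWKMBDHVN" else "ACDEFGHIKLMNPQRSTVWYXBZJUO*"
  bad <- regexpr(sprintf("[^%s]", alphabet), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stopf("non-IUPAC character in record '%s' at position %d", ids[i], bad[i])
  }
  setNames(seqs, ids)
}

#' Assemble coding transcript models from a GTF and reference sequences
#'
#' Reads `CDS` (and, when present, `three_prime_utr`) features from a GTF
#' file, splices them in transcript orientation (minus-strand sequence is
#' reverse-complemented) and returns one transcript model per
#' `transcript_id`. Transcript models are the substrate somatic variants
#' are applied to.
#'
#' @param path Path to a GTF file (attributes as `key "value";` pairs;
#'   GFF3 is not supported).
#' @param fasta Named character vector of reference sequences covering
#'   all intervals (as from [read_fasta()]), or a path to a FASTA file.
#' @param strict If `TRUE`, transcripts violating CDS invariants (length
#'   not a multiple of 3, missing ATG start, in-frame stop codon) are
#'   errors; by default they are skipped with a warning, as real
#'   annotations contain such cases.
#' @return Named list of transcript models. Each model is a list with
#'   fields `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `cds_intervals` (matrix of 1-based inclusive genomic `start`,`end`,
#'   ordered 5'->3' in transcript orientation), `cds_seq` (stranded,
#'   excludes the stop codon) and `utr3_seq` (stranded sequence
#'   immediately downstream of the CDS; empty when not annotated).
#' @export
read_gtf_cds <- function(path, fasta, strict = FALSE) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta) &&
      is.null(names(fasta))) {
    fasta <- read_fasta(fasta)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  feats <- df[df$type %in% c("CDS", "three_prime_utr"), , drop = FALSE]
  if (nrow(feats) == 0L) stopf("no CDS features found in %s", path)
  if (is.null(feats$transcript_id) || anyNA(feats$transcript_id)) {
    stopf("GTF record without a transcript_id attribute in %s", path)
  }
  if (is.null(feats$gene_id) || anyNA(feats$gene_id)) {
    stopf("GTF record without a gene_id attribute in %s", path)
  }
  out <- list()
  for (tid in unique(feats$transcript_id)) {
    rows <- feats[feats$transcript_id == tid, , drop = FALSE]
    tx <- tryCatch(
      assemble_transcript(tid, rows, fasta),
      error = function(e) e
    )
    if (inherits(tx, "error")) {
      if (strict) stop(tx)
      warnf("skipping transcript %s: %s", tid, conditionMessage(tx))
      next
    }
    out[[tid]] <- tx
  }
  out
}

# Build one transcript model from its GTF rows; errors on any invariant
# violation (the caller decides whether that is fatal).
assemble_transcript <- function(tid, rows, fasta) {
  chrom <- unique(rows$seqnames)
  strand <- unique(rows$strand)
  if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-")) {
    stopf("inconsistent chrom/strand for transcript %s", tid)
  }
  if (!chrom %in% names(fasta)) stopf("sequence '%s' absent from FASTA", chrom)
  contig <- fasta[[chrom]]
  cds <- rows[rows$type == "CDS", , drop = FALSE]
  utr <- rows[rows$type == "three_prime_utr", , drop = FALSE]
  if (nrow(cds) == 0L) stopf("transcript %s has no CDS rows", tid)
  if (any(cds$start > cds$end) || any(cds$start < 1L) ||
      any(cds$end > nchar(contig))) {
    stopf("CDS interval outside sequence bounds for %s", tid)
  }
  ord <- order(cds$start)
  cds <- cds[ord, , drop = FALSE]
  if (any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stopf("overlapping CDS intervals for %s", tid)
  }
  # transcript orientation: ascending genomic for +, descending for -
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  pieces <- substring(contig, cds$start, cds$end)
  if (strand == "-") pieces <- vapply(pieces, revcomp, character(1))
  cds_seq <- paste(pieces, collapse = "")
  utr3_seq <- ""
  if (nrow(utr) > 0L) {
    ordu <- order(utr$start)
    utr <- utr[ordu, , drop = FALSE]
    if (strand == "-") utr <- utr[rev(seq_len(nrow(utr))), , drop = FALSE]
    up <- substring(contig, utr$start, utr$end)
    if (strand == "-") up <- vapply(up, revcomp, character(1))
    utr3_seq <- paste(up, collapse = "")
  }
  validate_cds(tid, cds_seq)
  structure(
    list(transcript_id = tid,
         gene_id = cds$gene_id[1],
         chrom = chrom,
         strand = strand,
         cds_intervals = cbind(start = cds$start, end = cds$end),
         cds_seq = cds_seq,
         utr3_seq = utr3_seq),
    class = "transcript_model"
  )
}

validate_cds <- function(tid, cds_seq) {
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) stopf("CDS length %d not a multiple of 3", n)
  if (substr(cds_seq, 1L, 3L) != "ATG") stopf("CDS does not start with ATG")
  codons <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (any(codons %in% c("TAA", "TAG", "TGA"))) {
    stopf("CDS contains an in-frame stop codon")
  }
  invisible(TRUE)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s strand %s, CDS %d nt, 3'UTR %d nt>\n",
              x$transcript_id, x$gene_id, x$chrom,
              paste(apply(x$cds_intervals, 1, paste, collapse = "-"),
                    collapse = ","),
              x$strand, nchar(x$cds_seq), nchar(x$utr3_seq)))
  invisible(x)
}

#' Read somatic variants from a VCF file
#'
#' Loads a VCF v4.x file and returns one row per record for the named
#' sample, with altered-read support taken from the `AD` FORMAT field
#' (ref,alt depths). Multi-allelic records are rejected: decompose them
#' upstream so germline allele matching stays unambiguous.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip-compressed).
#' @param sample Sample name whose `AD` field supplies `alt_reads`.
#' @return A data frame of somatic variants with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `vclass` (`SNV`/`insertion`/`deletion`),
#'   `alt_reads` and `sample`.
#' @export
read_vcf <- function(path, sample) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  if (nrow(vcf) == 0L) return(empty_variants())
  if (!sample %in% colnames(vcf)) {
    stopf("sample '%s' not present in %s (samples: %s)", sample, path,
          paste(colnames(vcf), collapse = ", "))
  }
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno)) stopf("VCF %s has no AD FORMAT field", path)
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  if (any(nalt != 1L)) {
    stopf("multi-allelic record at %s: decompose the VCF first",
          rownames(vcf)[which(nalt != 1L)[1]])
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(altl))
  ad <- geno$AD[, sample]
  alt_reads <- vapply(seq_along(ad), function(i) {
    x <- ad[[i]]
    if (is.null(x) || length(x) < 2L || anyNA(x)) {
      stopf("missing AD for sample '%s' at record %s", sample,
            rownames(vcf)[i])
    }
    as.integer(x[2])
  }, integer(1))
  vclass <- classify_alleles(chrom, pos, ref, alt)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = vclass, alt_reads = alt_reads, sample = sample,
             row.names = NULL, stringsAsFactors = FALSE)
}

classify_alleles <- function(chrom, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  bad <- which(ref == alt)
  if (length(bad)) stopf("ref equals alt at %s:%d", chrom[bad[1]], pos[bad[1]])
  vclass <- ifelse(nr == 1L & na == 1L, "SNV",
                   ifelse(na > nr, "insertion",
                          ifelse(nr > na, "deletion", NA_character_)))
  if (anyNA(vclass)) {
    i <- which(is.na(vclass))[1]
    stopf("unsupported multi-nucleotide substitution at %s:%d (%s>%s)",
          chrom[i], pos[i], ref[i], alt[i])
  }
  indel <- vclass != "SNV"
  anch <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  if (any(indel & !anch)) {
    i <- which(indel & !anch)[1]
    stopf("indel at %s:%d is not anchored on a shared first base (%s>%s); left-align the VCF",
          chrom[i], pos[i], ref[i], alt[i])
  }
  vclass
}

#' Read an RSEM-style gene expression table
#'
#' @param path TSV with at least columns `gene_id` and `TPM` (extra
#'   columns are ignored).
#' @return Named numeric vector of TPM values keyed by `gene_id`.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "TPM") %in% names(df))) {
    stopf("expression table %s must have gene_id and TPM columns (found: %s)",
          path, paste(names(df), collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stopf("duplicate gene_id '%s' in %s", df$gene_id[duplicated(df$gene_id)][1],
          path)
  }
  tpm <- as.numeric(df$TPM)
  if (anyNA(tpm) || any(tpm < 0)) stopf("TPM must be non-negative in %s", path)
  setNames(tpm, df$gene_id)
}

# Columns of the final catalog, in output order.
CATALOG_COLUMNS <- c("peptide", "length", "allele", "percent_rank", "ic50_nm",
                     "gene_id", "transcript_id", "variant", "vclass", "tpm",
                     "wes_alt_reads", "rna_alt_reads", "class")

#' Write a neoantigen catalog to a TSV file
#'
#' One row per (peptide, allele), deterministically sorted by
#' `(gene_id, variant, peptide, allele)` so that identical inputs always
#' produce byte-identical files.
#'
#' @param records Catalog data frame (see [build_catalog()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  if (nrow(records) > 0) {
    miss <- setdiff(CATALOG_COLUMNS, names(records))
    if (length(miss)) stopf("catalog is missing columns: %s",
                            paste(miss, collapse = ", "))
    records <- records[order(records$gene_id, records$variant,
                             records$peptide, records$allele), CATALOG_COLUMNS]
  } else {
    records <- as.data.frame(setNames(rep(list(character(0)), length(CATALOG_COLUMNS)),
                                      CATALOG_COLUMNS))
  }
  lines <- paste(CATALOG_COLUMNS, collapse = "\t")
  if (nrow(records) > 0) {
    body <- apply(records, 1, function(r) {
      r <- as.list(r)
      paste(c(r$peptide, r$length, r$allele, fmt_num(as.numeric(r$percent_rank)),
              fmt_num(as.numeric(r$ic50_nm)), r$gene_id, r$transcript_id,
              r$variant, r$vclass, fmt_num(as.numeric(r$tpm)),
              r$wes_alt_reads, r$rna_alt_reads, r$class), collapse = "\t")
    })
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a catalog TSV written by [write_catalog()]
#'
#' @param path Catalog TSV path.
#' @return Catalog data frame with typed columns.
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(peptide = "character", length = "integer",
                                  allele = "character", percent_rank = "numeric",
                                  ic50_nm = "numeric", gene_id = "character",
                                  transcript_id = "character",
                                  variant = "character", vclass = "character",
                                  tpm = "numeric", wes_alt_reads = "integer",
                                  rna_alt_reads = "integer", class = "character"))
  miss <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(miss)) stopf("not a catalog file (%s missing)", paste(miss, collapse = ", "))
  df
}

# Minimal VCF v4.2 writer used by the synthetic-data generators (readers
# always go through VariantAnnotation). One sample column with GT:AD.
write_simple_vcf <- function(variants, path, sample, contigs = NULL,
                             ref_reads = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neoforge-simulator",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          unname(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    if (is.null(ref_reads)) ref_reads <- rep(20L, nrow(variants))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t0/1:%d,%d",
                    variants$chrom, variants$pos, variants$ref, variants$alt,
                    ref_reads[ord], variants$alt_reads)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
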