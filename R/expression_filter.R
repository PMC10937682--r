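# The variant-evidence filter cascade: germline subtraction against the
# matched normal, the WES altered-read support threshold (>= 5), RNA-seq
# altered-allele validation anchored on the WES calls (>= 3), and
# attachment of gene-level TPM. All matching is allele-exact
# (chrom, pos, ref, alt): position-only matching would delete genuine
# somatic alleles at polymorphic sites.

#' Subtract germline variants using the matched normal
#'
#' Removes tumour variants that have an exact (chrom, pos, ref, alt)
#' match in the normal sample; order is preserved.
#'
#' @param tumor,normal Somatic variant data frames from [read_vcf()].
#' @return The somatic subset of `tumor`.
#' @export
subtract_germline <- function(tumor, normal) {
  if (nrow(tumor) == 0L || nrow(normal) == 0L) return(tumor)
  out <- tumor[!variant_key(tumor) %in% variant_key(normal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants on WES altered-read support
#'
#' Keeps variants supported by `min_alt` or more altered reads
#' (inclusive threshold).
#'
#' @param vars Variant data frame with an `alt_reads` column.
#' @param min_alt Minimum altered-read count (default 5).
#' @return The supported subset of `vars`.
#' @export
filter_wes_support <- function(vars, min_alt = 5L) {
  stopifnot(min_alt >= 0)
  out <- vars[vars$alt_reads >= min_alt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate WES variants against RNA-seq variant calls
#'
#' The join is anchored on the WES-passed set: a WES variant is kept only
#' if the same allele was called in the RNA-seq data with at least
#' `min_alt` altered reads (inclusive); RNA-only variants are never
#' emitted.
#'
#' @param wes_passed WES variants surviving [subtract_germline()] and
#'   [filter_wes_support()].
#' @param rna RNA-seq variant calls from [read_vcf()].
#' @param min_alt Minimum RNA altered-read count (default 3).
#' @return A variant-evidence data frame: the surviving variants with
#'   columns `wes_alt_reads` and `rna_alt_reads` (and `tpm = NA` until
#'   [attach_tpm()] runs).
#' @export
validate_rna <- function(wes_passed, rna, min_alt = 3L) {
  stopifnot(min_alt >= 0)
  rna_ok <- rna[rna$alt_reads >= min_alt, , drop = FALSE]
  idx <- match(variant_key(wes_passed), variant_key(rna_ok))
  keep <- !is.na(idx)
  ev <- wes_passed[keep, , drop = FALSE]
  ev$wes_alt_reads <- ev$alt_reads
  ev$rna_alt_reads <- rna_ok$alt_reads[idx[keep]]
  ev$alt_reads <- NULL
  ev$tpm <- rep(NA_real_, nrow(ev))
  rownames(ev) <- NULL
  ev
}

#' Attach gene-level TPM to variant evidence
#'
#' @param ev Variant-evidence data frame carrying a `transcript_id`
#'   column (see [annotate_transcripts()]).
#' @param expr Named TPM vector from [read_expression()].
#' @param tx2gene Named character vector mapping transcript_id to
#'   gene_id; every evidence transcript must map (error otherwise).
#'   Genes absent from the expression table get TPM 0 with a warning.
#' @return `ev` with `gene_id` and `tpm` filled in.
#' @export
attach_tpm <- function(ev, expr, tx2gene) {
  if (nrow(ev) == 0L) { ev$tpm <- numeric(0); return(ev) }
  if (is.null(ev$transcript_id)) {
    stopf("evidence has no transcript_id column; run annotate_transcripts() first")
  }
  gene <- tx2gene[ev$transcript_id]
  if (anyNA(gene)) {
    stopf("transcript '%s' has no gene mapping",
          ev$transcript_id[which(is.na(gene))[1]])
  }
  ev$gene_id <- unname(gene)
  tpm <- expr[ev$gene_id]
  if (anyNA(tpm)) {
    missing_genes <- unique(ev$gene_id[is.na(tpm)])
    warnf("gene(s) absent from expression table, TPM set to 0: %s",
          paste(missing_genes, collapse = ", "))
    tpm[is.na(tpm)] <- 0
  }
  ev$tpm <- unname(tpm)
  ev
}

#' Locate each variant in a set of transcript models
#'
#' Adds `transcript_id` and `gene_id` columns by finding, for every
#' variant, the transcript whose CDS contains it. Variants falling in no
#' transcript's CDS are dropped with a log message; a variant hitting
#' several transcripts is assigned to each (one row per hit).
#'
#' @param vars Variant data frame.
#' @param txs Named list of transcript models from [read_gtf_cds()].
#' @return `vars` with `transcript_id` and `gene_id` columns.
#' @export
annotate_transcripts <- function(vars, txs) {
  rows <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, , drop = FALSE]
    hit <- FALSE
    for (tx in txs) {
      if (v$chrom != tx$chrom) next
      if (is.na(genomic_to_cds(tx, v$pos))) next
      r <- v
      r$transcript_id <- tx$transcript_id
      r$gene_id <- tx$gene_id
      rows[[length(rows) + 1L]] <- r
      hit <- TRUE
    }
    if (!hit) nf_log("variant %s falls in no CDS; dropped", variant_key(v))
  }
  if (length(rows) == 0L) {
    vars <- vars[0, , drop = FALSE]
    vars$transcript_id <- character(0)
    vars$gene_id <- character(0)
    return(vars)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
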