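# Joining peptides, binding predictions and expression evidence into the
# final neoantigen catalog, and classifying records as shared between the
# two cell lines or unique to one of them. Classification is keyed on
# peptide sequence, not variant identity: identical peptides arising from
# different genomic events are immunologically one entity.

#' Build a per-line neoantigen catalog
#'
#' Inner-joins peptides to their variant evidence and to their binding
#' predictions, keeps strong binders only, retains the best (minimum
#' percent-rank) allele per peptide, and collapses duplicate peptide
#' sequences to one record per (peptide, line).
#'
#' @param evidence Variant-evidence data frame from [attach_tpm()].
#' @param peptides Peptide data frame from [enumerate_neoepitopes()]
#'   (rows must derive from `evidence`'s variants).
#' @param bindings Binding predictions covering every peptide (a peptide
#'   with no prediction at all is an error: the predictor must be total).
#' @param line Sample label for this catalog.
#' @param rank_max Strong-binder threshold on percent rank (default 0.5).
#' @return Catalog data frame (columns of [write_catalog()] plus `line`);
#'   `class` is `"unassigned"` until [classify_shared_unique()] runs.
#' @export
build_catalog <- function(evidence, peptides, bindings, line,
                          rank_max = 0.5) {
  empty <- data.frame(
    peptide = character(), length = integer(), allele = character(),
    percent_rank = numeric(), ic50_nm = numeric(), gene_id = character(),
    transcript_id = character(), variant = character(), vclass = character(),
    tpm = numeric(), wes_alt_reads = integer(), rna_alt_reads = integer(),
    class = character(), line = character(), stringsAsFactors = FALSE)
  if (nrow(evidence) == 0L || nrow(peptides) == 0L) return(empty)
  idx <- match(variant_key(peptides), variant_key(evidence))
  pep <- peptides[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(pep) == 0L) return(empty)
  uncovered <- setdiff(pep$sequence, bindings$peptide)
  if (length(uncovered)) {
    stopf("no binding prediction for peptide(s): %s",
          paste(utils::head(uncovered, 3), collapse = ", "))
  }
  strong <- best_binding(filter_strong_binders(bindings, rank_max))
  bidx <- match(pep$sequence, strong$peptide)
  keep <- !is.na(bidx)
  pep <- pep[keep, , drop = FALSE]
  ev <- evidence[idx[keep], , drop = FALSE]
  bb <- strong[bidx[keep], , drop = FALSE]
  out <- data.frame(
    peptide = pep$sequence, length = nchar(pep$sequence),
    allele = bb$allele, percent_rank = bb$percent_rank,
    ic50_nm = bb$ic50_nm, gene_id = ev$gene_id,
    transcript_id = ev$transcript_id,
    variant = variant_key(pep), vclass = pep$vclass, tpm = ev$tpm,
    wes_alt_reads = ev$wes_alt_reads, rna_alt_reads = ev$rna_alt_reads,
    class = "unassigned", line = line, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$variant, out$peptide), , drop = FALSE]
  dup <- duplicated(out$peptide)
  if (any(dup)) {
    nf_log("line %s: %d peptide(s) arise from multiple variants; keeping first provenance of each (%s)",
           line, sum(dup), paste(unique(out$peptide[dup]), collapse = ", "))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify neoantigens as shared or unique between two catalogs
#'
#' Membership is keyed on peptide sequence: `shared` is the
#' intersection, `unique_A`/`unique_B` the set differences. The three
#' groups are pairwise disjoint and partition the union.
#'
#' @param cat_a,cat_b Catalogs from [build_catalog()].
#' @return List with elements `shared`, `unique_A`, `unique_B` (catalog
#'   subsets with `class` set; shared records are reported from catalog
#'   A) and `counts` (named integer vector, the Venn counts).
#' @export
classify_shared_unique <- function(cat_a, cat_b) {
  in_b <- cat_a$peptide %in% cat_b$peptide
  in_a <- cat_b$peptide %in% cat_a$peptide
  shared <- cat_a[in_b, , drop = FALSE]
  unique_a <- cat_a[!in_b, , drop = FALSE]
  unique_b <- cat_b[!in_a, , drop = FALSE]
  if (nrow(shared)) shared$class <- "shared"
  if (nrow(unique_a)) unique_a$class <- "unique_A"
  if (nrow(unique_b)) unique_b$class <- "unique_B"
  rownames(shared) <- rownames(unique_a) <- rownames(unique_b) <- NULL
  list(shared = shared, unique_A = unique_a, unique_B = unique_b,
       counts = c(shared = nrow(shared), unique_A = nrow(unique_a),
                  unique_B = nrow(unique_b)))
}

#' Expression/affinity scatter table for a classified catalog
#'
#' One row per record with the quantities plotted in the TPM-vs-IC50
#' scatter; log transforms are left to plotting code.
#'
#' @param records Catalog data frame (class column populated).
#' @return Data frame with columns `peptide`, `class`, `tpm`, `ic50_nm`.
#' @export
scatter_table <- function(records) {
  data.frame(peptide = records$peptide, class = records$class,
             tpm = records$tpm, ic50_nm = records$ic50_nm,
             stringsAsFactors = FALSE)
}
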