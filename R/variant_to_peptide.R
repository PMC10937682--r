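# Codon-aware application of somatic variants to coding transcripts,
# translation with frameshift read-through, and enumeration of candidate
# mutant peptides of length 8-11 overlapping mutated residues.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide string with the standard genetic code
#'
#' Codons are read 5'->3' from position 1; a trailing partial codon is
#' ignored; translation stops before the first stop codon.
#'
#' @param nt Non-empty nucleotide string (A/C/G/T only in consumed
#'   codons; an ambiguity code such as `N` inside a consumed codon is an
#'   error rather than a guessed residue).
#' @return Amino-acid string (possibly empty, if the first codon is a
#'   stop).
#' @export
translate_cds <- function(nt) {
  if (!is.character(nt) || length(nt) != 1L || !nzchar(nt)) {
    stopf("translate_cds() needs a non-empty nucleotide string")
  }
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) {
    aa <- aa[seq_len(stop_at - 1L)]
    codons <- codons[seq_len(stop_at - 1L)]
  }
  if (anyNA(aa)) {
    stopf("untranslatable codon '%s' (ambiguity code?) at codon %d",
          codons[which(is.na(aa))[1]], which(is.na(aa))[1])
  }
  paste(aa, collapse = "")
}

# Map a genomic position to its 1-based CDS coordinate, or NA when the
# position falls outside every CDS interval. Intervals are stored 5'->3'
# in transcript orientation.
genomic_to_cds <- function(tx, gpos) {
  offset <- 0L
  for (i in seq_len(nrow(tx$cds_intervals))) {
    s <- tx$cds_intervals[i, "start"]; e <- tx$cds_intervals[i, "end"]
    if (gpos >= s && gpos <= e) {
      return(if (tx$strand == "+") offset + (gpos - s + 1L)
             else offset + (e - gpos + 1L))
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

# Inverse of genomic_to_cds.
cds_to_genomic <- function(tx, cpos) {
  offset <- 0L
  for (i in seq_len(nrow(tx$cds_intervals))) {
    s <- tx$cds_intervals[i, "start"]; e <- tx$cds_intervals[i, "end"]
    w <- e - s + 1L
    if (cpos <= offset + w) {
      k <- cpos - offset
      return(if (tx$strand == "+") s + k - 1L else e - k + 1L)
    }
    offset <- offset + w
  }
  stopf("CDS position %d outside transcript %s", cpos, tx$transcript_id)
}

#' Apply one somatic variant to a transcript model
#'
#' Maps the variant into CDS coordinates (reverse-complementing alleles
#' on minus-strand transcripts), edits the coding sequence and
#' translates. Frameshift indels read through the original coding frame
#' into the downstream 3' UTR sequence until the first stop codon (or the
#' end of the available sequence, with a warning).
#'
#' @param tx A transcript model from [read_gtf_cds()].
#' @param v A one-row somatic variant data frame (see [read_vcf()]).
#' @return A `mutant_protein` object (list with `transcript_id`,
#'   `gene_id`, `wt_aa`, `mut_aa`, `mut_span` (integer first/last mutated
#'   residue in `mut_aa`, or `NULL` when no residue changes),
#'   `consequence` and `variant`), or `NULL` when the variant lies
#'   outside the CDS.
#' @details Consequences: `missense`, `synonymous` (empty span),
#'   `stop_gain` (truncated protein, empty span: no novel residues),
#'   `inframe_indel` (span covers the altered run, or the two junction
#'   residues for a clean deletion) and `frameshift` (span runs from the
#'   first novel residue to the C-terminus). A ref allele that disagrees
#'   with the transcript sequence, or a variant spanning a CDS boundary,
#'   is an error.
#' @export
apply_variant <- function(tx, v) {
  stopifnot(inherits(tx, "transcript_model"), nrow(v) == 1L)
  if (v$chrom != tx$chrom) {
    nf_log("variant %s not on transcript %s contig; skipped",
           variant_key(v), tx$transcript_id)
    return(NULL)
  }
  span_g <- v$pos:(v$pos + nchar(v$ref) - 1L)
  cmap <- vapply(span_g, genomic_to_cds, integer(1), tx = tx)
  if (all(is.na(cmap))) {
    nf_log("variant %s outside CDS of %s; skipped", variant_key(v),
           tx$transcript_id)
    return(NULL)
  }
  if (anyNA(cmap) || (length(cmap) > 1L && any(abs(diff(cmap)) != 1L))) {
    stopf("variant %s spans a CDS boundary of %s", variant_key(v),
          tx$transcript_id)
  }
  c1 <- min(cmap); c2 <- max(cmap)
  seg <- substr(tx$cds_seq, c1, c2)
  ref_t <- if (tx$strand == "+") v$ref else revcomp(v$ref)
  alt_t <- if (tx$strand == "+") v$alt else revcomp(v$alt)
  if (seg != ref_t) {
    stopf("ref allele mismatch for %s on %s: transcript has '%s' at CDS %d-%d",
          variant_key(v), tx$transcript_id, seg, c1, c2)
  }
  mut_cds <- paste0(substr(tx$cds_seq, 1L, c1 - 1L), alt_t,
                    substr(tx$cds_seq, c2 + 1L, nchar(tx$cds_seq)))
  wt_aa <- translate_cds(tx$cds_seq)
  shift <- (nchar(v$alt) - nchar(v$ref)) %% 3L
  if (shift != 0L) {
    read_through <- paste0(mut_cds, tx$utr3_seq)
    if (!has_downstream_stop(read_through)) {
      warnf("frameshift %s on %s reaches the end of the transcript without a stop codon",
            variant_key(v), tx$transcript_id)
    }
    mut_aa <- translate_cds(read_through)
    consequence <- "frameshift"
  } else {
    mut_aa <- translate_cds(mut_cds)
    consequence <- NA_character_
  }
  if (shift != 0L) {
    span <- diff_span_frameshift(tx$cds_seq, mut_cds, mut_aa)
  } else if (v$vclass == "SNV") {
    res <- diff_span_snv(wt_aa, mut_aa)
    span <- res$span
    consequence <- res$consequence
  } else {
    nd3 <- (nchar(v$alt) - nchar(v$ref)) %/% 3L
    span <- diff_span_inframe(wt_aa, mut_aa, nd3)
    consequence <- "inframe_indel"
  }
  structure(
    list(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
         wt_aa = wt_aa, mut_aa = mut_aa, mut_span = span,
         consequence = consequence, variant = v),
    class = "mutant_protein"
  )
}

has_downstream_stop <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n == 0L) return(FALSE)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  any(codons %in% STOP_CODONS)
}

# Mutated-residue spans in mut_aa under a longest-common-prefix/suffix
# alignment. Frameshift spans run from the first novel residue to the
# C-terminus; a clean in-frame deletion (no residue differs) is assigned
# the two junction residues, since novel junction peptides can still
# arise there; truncating events contribute no novel residues at all.

# Frameshift span starts at the codon containing the first changed
# nucleotide (residues upstream are untouched by construction) and runs
# to the C-terminus. NULL when the shifted frame hits an immediate stop.
diff_span_frameshift <- function(cds, mut_cds, mut_aa) {
  nm <- nchar(mut_aa)
  if (nm == 0L) return(NULL)
  np <- common_prefix_len(cds, mut_cds)
  fs_res <- np %/% 3L + 1L
  if (fs_res > nm) return(NULL)
  c(fs_res, nm)
}

diff_span_snv <- function(wt, mut) {
  if (wt == mut) return(list(span = NULL, consequence = "synonymous"))
  nw <- nchar(wt); nm <- nchar(mut)
  p <- common_prefix_len(wt, mut)
  if (nm < nw && p >= nm) return(list(span = NULL, consequence = "stop_gain"))
  list(span = c(p + 1L, p + 1L), consequence = "missense")
}

diff_span_inframe <- function(wt, mut, nd3) {
  nw <- nchar(wt); nm <- nchar(mut)
  if (nm == 0L) return(NULL)
  p <- common_prefix_len(wt, mut)
  if (nm != nw + nd3) {
    # premature stop: the wild-type C-terminus is lost, so suffix
    # alignment does not apply; novel residues run from p+1 to the end
    if (p >= nm) return(NULL)
    return(c(p + 1L, nm))
  }
  s <- common_suffix_len(wt, mut, max_len = min(nw, nm) - p)
  start <- p + 1L; end <- nm - s
  if (start <= end) return(c(start, end))
  if (nd3 < 0L) {
    return(c(max(1L, p), min(nm, p + 1L)))    # clean deletion: junction
  }
  NULL
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

common_suffix_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

#' @export
print.mutant_protein <- function(x, ...) {
  span <- if (is.null(x$mut_span)) "none" else paste(x$mut_span, collapse = "-")
  cat(sprintf("<mutant protein %s (%s): %s, %d aa, mutated span %s>\n",
              x$transcript_id, variant_key(x$variant), x$consequence,
              nchar(x$mut_aa), span))
  invisible(x)
}

#' Enumerate candidate mutant peptides (8-11-mers) from a mutant protein
#'
#' Slides windows of each requested length across the mutant protein and
#' keeps those that (i) contain at least one mutated residue and (ii) do
#' not occur anywhere in the wild-type protein of the same transcript
#' (wild-type subtraction). Output is deduplicated on sequence (keeping
#' the smallest window start) and ordered by (length, window_start).
#'
#' @param mp A `mutant_protein` from [apply_variant()].
#' @param lengths Integer window lengths, default `8:11`.
#' @param wt_extra Optional character vector of additional wild-type
#'   protein sequences to subtract against (e.g. a whole proteome);
#'   windows occurring in any of them are also removed.
#' @return Data frame of peptides with columns `sequence`, `length`,
#'   `window_start`, `n_mut_residues`, `transcript_id`, `gene_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `vclass`. Empty for synonymous and
#'   stop-gain input.
#' @export
enumerate_neoepitopes <- function(mp, lengths = 8:11, wt_extra = character(0)) {
  stopifnot(inherits(mp, "mutant_protein"))
  empty <- data.frame(sequence = character(), length = integer(),
                      window_start = integer(), n_mut_residues = integer(),
                      stringsAsFactors = FALSE)
  out <- empty
  if (!is.null(mp$mut_span)) {
    nm <- nchar(mp$mut_aa)
    lengths <- sort(unique(as.integer(lengths)))
    rows <- list()
    for (L in lengths) {
      if (L < 1L || L > nm) next
      first <- max(1L, mp$mut_span[1] - L + 1L)
      last <- min(nm - L + 1L, mp$mut_span[2])
      if (first > last) next
      starts <- first:last
      seqs <- substring(mp$mut_aa, starts, starts + L - 1L)
      n_mut <- pmin(starts + L - 1L, mp$mut_span[2]) -
        pmax(starts, mp$mut_span[1]) + 1L
      keep <- !vapply(seqs, grepl, logical(1), x = mp$wt_aa, fixed = TRUE)
      if (length(wt_extra)) {
        keep <- keep & !vapply(seqs, function(s) {
          any(vapply(wt_extra, grepl, logical(1), pattern = s, fixed = TRUE))
        }, logical(1))
      }
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = unname(seqs[keep]), length = L,
        window_start = starts[keep], n_mut_residues = n_mut[keep],
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out <- out[!duplicated(out$sequence), , drop = FALSE]
    }
  }
  v <- mp$variant
  out$transcript_id <- rep(mp$transcript_id, nrow(out))
  out$gene_id <- rep(mp$gene_id, nrow(out))
  out$chrom <- rep(v$chrom, nrow(out))
  out$pos <- rep(v$pos, nrow(out))
  out$ref <- rep(v$ref, nrow(out))
  out$alt <- rep(v$alt, nrow(out))
  out$vclass <- rep(v$vclass, nrow(out))
  rownames(out) <- NULL
  out
}
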