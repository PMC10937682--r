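# Independent brute-force oracle for the peptide-enumeration stage. This
# file must stay naive and self-contained: it rebuilds the mutant protein
# by plain string editing, translates with its own hard-coded codon
# table, enumerates every 8-11-mer substring and keeps those absent from
# the wild-type protein. The pipeline implementation must agree with it
# on every generated dataset; nothing here may call into
# variant_to_peptide code.

NAIVE_BASES <- c(T = 0L, C = 1L, A = 2L, G = 3L)
NAIVE_AA <- strsplit(paste0(
  "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]

naive_translate <- function(nt) {
  b <- NAIVE_BASES[strsplit(nt, "")[[1]]]
  out <- character(0)
  i <- 1L
  while (i + 2L <= length(b)) {
    aa <- NAIVE_AA[16L * b[i] + 4L * b[i + 1L] + b[i + 2L] + 1L]
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# Expected peptide set for one transcript-space edit: replace CDS
# positions tstart..tend (tstart > tend means pure insertion before
# tstart) with `repl`, read through into the downstream UTR when the
# frame shifts, and return every 8-11-mer of the mutant protein that is
# not a substring of the wild-type protein.
naive_expected_peptides <- function(cds, utr3, tstart, tend, repl,
                                    lengths = 8:11) {
  mut <- paste0(substr(cds, 1L, tstart - 1L), repl,
                substr(cds, tend + 1L, nchar(cds)))
  if (nchar(mut) %% 3L != 0L) mut <- paste0(mut, utr3)
  wt_aa <- naive_translate(cds)
  mut_aa <- naive_translate(mut)
  found <- character(0)
  for (L in lengths) {
    if (L > nchar(mut_aa)) next
    for (s in seq_len(nchar(mut_aa) - L + 1L)) {
      pep <- substr(mut_aa, s, s + L - 1L)
      if (!grepl(pep, wt_aa, fixed = TRUE)) found <- c(found, pep)
    }
  }
  unique(found)
}
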