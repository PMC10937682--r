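# Synthetic-data generators: a toy transcriptome (FASTA + GTF), planted
# somatic/germline variants with read support (VCFs for two tumour lines
# and the matched normal), RNA-seq validation calls and expression
# tables, and a survival cohort with a latent cDC1 factor. Every
# generator is a pure function of its seed and parameters, writes only
# the standard formats handled by the readers in this package, and
# records ground truth (including expected peptides computed by the
# independent naive oracle, never by the pipeline under test).

# Amino acids free of every toy-predictor anchor residue (no F/Y/N for
# position 5, no L/M/I/V for the C-terminus). A transcriptome restricted
# to these residues can only present strong binders that were explicitly
# planted.
ANCHOR_FREE_AA <- c("A", "G", "P", "S", "T", "D", "E", "K", "R", "Q", "H",
                    "W", "C")

# Stop codons in all three frames; appended to every 3' UTR so that
# frameshift read-through always terminates inside the transcript.
UTR_TERMINATOR <- "TAAATAAATAA"

codon_pool <- function(aa_alphabet) {
  gc <- Biostrings::GENETIC_CODE
  keep <- gc != "*"
  if (aa_alphabet == "anchor_free") keep <- keep & gc %in% ANCHOR_FREE_AA
  names(gc)[keep]
}

#' Generate a toy transcriptome (FASTA + GTF + transcript models)
#'
#' Each gene gets its own contig carrying one transcript: a CDS that
#' starts with ATG, contains no in-frame stop and excludes the stop
#' codon, followed by a 3' UTR that ends in stop codons in all three
#' frames (so frameshift translation always terminates). Strands
#' alternate between + and -, and every other transcript is split into
#' two CDS exons to exercise splicing.
#'
#' @param seed Integer seed; the generator is a pure function of seed
#'   and parameters.
#' @param n_genes Number of genes/transcripts.
#' @param cds_len_range Range (nt) for CDS lengths; values are rounded to
#'   multiples of 3, minimum 60.
#' @param utr3_len Length (nt) of the random part of each 3' UTR.
#' @param aa_alphabet `"full"` (all residues) or `"anchor_free"` (no
#'   toy-predictor anchor residues; used when planting variants that must
#'   yield exactly one strong binder each).
#' @param out_dir If non-NULL, write `ref.fa` and `annot.gtf` there.
#' @return List with `txs` (named list of transcript models), `fasta`
#'   (named sequences), `tx2gene`, and `paths` (when files were
#'   written).
#' @export
generate_transcriptome <- function(seed, n_genes = 12,
                                   cds_len_range = c(150, 300),
                                   utr3_len = 60,
                                   aa_alphabet = c("full", "anchor_free"),
                                   out_dir = NULL) {
  aa_alphabet <- match.arg(aa_alphabet)
  stopifnot(n_genes >= 1, cds_len_range[1] >= 60)
  pool <- codon_pool(aa_alphabet)
  withr::with_seed(seed, {
    fasta <- character(0)
    txs <- list()
    gtf_lines <- character(0)
    for (i in seq_len(n_genes)) {
      tid <- sprintf("TX%03d", i)
      gid <- sprintf("GENE%03d", i)
      chrom <- sprintf("chr%03d", i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      two_exons <- i %% 4L %in% c(0L, 1L)
      n_codons <- sample(seq(ceiling(cds_len_range[1] / 3),
                             floor(cds_len_range[2] / 3)), 1L)
      cds_seq <- paste0("ATG", paste(sample(pool, n_codons - 1L,
                                            replace = TRUE), collapse = ""))
      utr3_seq <- paste0(paste(sample(c("A", "C", "G", "T"), utr3_len,
                                      replace = TRUE), collapse = ""),
                         UTR_TERMINATOR)
      # plus-orientation layout: pad | exon1 [| intron | exon2] | utr3 | pad
      pad <- 10L
      n_cds <- nchar(cds_seq)
      if (two_exons) {
        cut <- 3L * sample(seq(10L, n_codons - 10L), 1L)
        intron <- paste(sample(c("A", "C", "G", "T"), 15L, replace = TRUE),
                        collapse = "")
        layout_seq <- paste0(strrep("A", pad), substr(cds_seq, 1L, cut),
                             intron, substr(cds_seq, cut + 1L, n_cds),
                             utr3_seq, strrep("A", pad))
        exons <- rbind(c(pad + 1L, pad + cut),
                       c(pad + cut + 16L, pad + n_cds + 15L))
        utr_iv <- c(pad + n_cds + 16L, pad + n_cds + 15L + nchar(utr3_seq))
      } else {
        layout_seq <- paste0(strrep("A", pad), cds_seq, utr3_seq,
                             strrep("A", pad))
        exons <- rbind(c(pad + 1L, pad + n_cds))
        utr_iv <- c(pad + n_cds + 1L, pad + n_cds + nchar(utr3_seq))
      }
      lc <- nchar(layout_seq)
      if (strand == "-") {
        contig <- revcomp(layout_seq)
        flip <- function(iv) c(lc - iv[2] + 1L, lc - iv[1] + 1L)
        exons <- t(apply(exons, 1L, flip))
        exons <- exons[order(exons[, 1]), , drop = FALSE]
        utr_iv <- flip(utr_iv)
      } else {
        contig <- layout_seq
      }
      fasta[chrom] <- contig
      # transcript-orientation interval order: descending genomic on -
      tx_exons <- if (strand == "-") {
        exons[rev(seq_len(nrow(exons))), , drop = FALSE]
      } else exons
      txs[[tid]] <- structure(
        list(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand,
             cds_intervals = cbind(start = tx_exons[, 1], end = tx_exons[, 2]),
             cds_seq = cds_seq, utr3_seq = utr3_seq),
        class = "transcript_model")
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      gtf_lines <- c(gtf_lines,
                     sprintf("%s\tneoforge\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                             chrom, exons[, 1], exons[, 2], strand, attr_str),
                     sprintf("%s\tneoforge\tthree_prime_utr\t%d\t%d\t.\t%s\t.\t%s",
                             chrom, utr_iv[1], utr_iv[2], strand, attr_str))
    }
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa_path <- file.path(out_dir, "ref.fa")
      gtf_path <- file.path(out_dir, "annot.gtf")
      write_fasta(fasta, fa_path)
      con <- file(gtf_path, open = "wb")
      writeLines(gtf_lines, con, sep = "\n")
      close(con)
      paths <- list(fasta = fa_path, gtf = gtf_path)
    }
    list(txs = txs, fasta = fasta,
         tx2gene = vapply(txs, `[[`, character(1), "gene_id"),
         paths = paths)
  })
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), width)
    writeLines(c(paste0(">", id), substring(s, starts, starts + width - 1L)),
               con, sep = "\n")
  }
  invisible(path)
}

# -- transcript-space edits -> genomic VCF alleles ---------------------------

same_exon <- function(tx, t1, t2) {
  g1 <- cds_to_genomic(tx, t1); g2 <- cds_to_genomic(tx, t2)
  abs(g1 - g2) == (t2 - t1)
}

# Anchored indel: after transcript CDS position t_anchor, delete the next
# n_del bases and insert `ins` (transcript-orientation sequence). Returns
# genomic chrom/pos/ref/alt in standard anchored VCF form.
tx_indel_to_variant <- function(tx, fasta, t_anchor, n_del, ins) {
  contig <- fasta[[tx$chrom]]
  if (tx$strand == "+") {
    pos <- cds_to_genomic(tx, t_anchor)
    ref <- substr(contig, pos, pos + n_del)
    alt <- paste0(substr(contig, pos, pos), ins)
  } else {
    pos <- cds_to_genomic(tx, t_anchor + n_del + 1L)
    ref <- substr(contig, pos, pos + n_del)
    alt <- paste0(substr(contig, pos, pos), revcomp(ins))
  }
  list(chrom = tx$chrom, pos = pos, ref = ref, alt = alt)
}

tx_snv_to_variant <- function(tx, t, alt_t) {
  ref_t <- substr(tx$cds_seq, t, t)
  stopifnot(ref_t != alt_t)
  pos <- cds_to_genomic(tx, t)
  if (tx$strand == "+") {
    list(chrom = tx$chrom, pos = pos, ref = ref_t, alt = alt_t)
  } else {
    list(chrom = tx$chrom, pos = pos, ref = revcomp(ref_t),
         alt = revcomp(alt_t))
  }
}

# -- variant planting --------------------------------------------------------

#' Plant somatic and germline variants into a toy transcriptome
#'
#' Produces tumour VCF call sets for two cell lines A and B, where line
#' B carries all of line A's somatic variants plus extra (mirroring a
#' hypermutated derivative of a parental line), plus a matched-normal
#' call set containing the germline variants (which also appear in both
#' tumour VCFs). WES altered-read counts are drawn from a Poisson
#' distribution (mean `mean_alt_reads`, floored at 5 so that planted
#' designs survive the support filter); a configurable fraction is
#' instead forced below 5 to exercise the filter boundary. Ground-truth
#' expected peptides are computed by the naive string-edit oracle.
#'
#' @param seed Integer seed.
#' @param txs Transcriptome from [generate_transcriptome()] (the full
#'   list, with `fasta`).
#' @param n_missense,n_synonymous,n_frameshift,n_inframe Somatic variant
#'   counts by consequence (frameshifts are 1-2 nt indels; in-frame
#'   indels are 3 nt).
#' @param n_germline Germline SNVs present in tumour and normal VCFs.
#' @param shared_fraction Fraction of somatic variants shared by line A
#'   (ignored when `strong_design` is given).
#' @param mean_alt_reads Poisson mean for WES altered-read counts.
#' @param frac_low_wes Fraction of somatic variants forced to 0-4
#'   altered reads in both lines.
#' @param strong_design Optional `list(shared = , unique_b = )`: plant
#'   that many in-frame 27-nt insertions, each encoding a distinct 9-mer
#'   with both toy-predictor anchors (F at position 5, L at the
#'   C-terminus), guaranteed to yield exactly one strong binder each
#'   when the transcriptome uses the `anchor_free` alphabet.
#' @param out_dir If non-NULL, write `tumor_a.vcf`, `tumor_b.vcf`,
#'   `normal.vcf` there.
#' @return List with per-sample variant data frames (`tumor_a`,
#'   `tumor_b`, `normal`), `truth` (planted table, expected peptides per
#'   variant from the oracle, design counts) and `paths`.
#' @export
plant_variants <- function(seed, txs, n_missense = 4, n_synonymous = 2,
                           n_frameshift = 2, n_inframe = 0, n_germline = 2,
                           shared_fraction = 0.5, mean_alt_reads = 20,
                           frac_low_wes = 0, strong_design = NULL,
                           out_dir = NULL) {
  fasta <- txs$fasta
  models <- txs$txs
  withr::with_seed(seed, {
    used <- lapply(models, function(x) integer(0))  # occupied CDS positions
    planted <- list()

    reserve <- function(tid, lo, hi) {
      win <- lo:hi
      if (length(intersect(used[[tid]], win))) return(FALSE)
      used[[tid]] <<- c(used[[tid]], win)
      TRUE
    }

    pick_tx <- function() models[[sample(length(models), 1L)]]

    with_retries <- function(f, what, tries = 200L) {
      for (k in seq_len(tries)) {
        out <- f()
        if (!is.null(out)) return(out)
      }
      stopf("could not place a %s variant after %d attempts; transcriptome too small",
            what, tries)
    }

    plant_one <- function(kind) {
      with_retries(function() {
        tx <- pick_tx()
        n <- nchar(tx$cds_seq)
        n_cod <- n %/% 3L
        if (n_cod < 12L) return(NULL)
        j <- sample(seq(3L, n_cod - 2L), 1L)   # codon index, away from ends
        t0 <- 3L * (j - 1L) + 1L               # first nt of codon j
        if (kind %in% c("missense", "synonymous", "germline")) {
          codon <- substr(tx$cds_seq, t0, t0 + 2L)
          cands <- codon_variants(codon, kind)
          if (nrow(cands) == 0L) return(NULL)
          pick <- cands[sample(nrow(cands), 1L), ]
          t <- t0 + pick$offset
          if (!same_exon(tx, t, t)) return(NULL)
          if (!reserve(tx$transcript_id, t - 1L, t + 1L)) return(NULL)
          v <- tx_snv_to_variant(tx, t, pick$base)
          edit <- list(tstart = t, tend = t, repl = pick$base)
          vclass <- "SNV"
        } else if (kind == "frameshift") {
          n_del <- sample(c(0L, 1L, 2L), 1L, prob = c(0.4, 0.4, 0.2))
          ins <- if (n_del == 0L) {
            paste(sample(c("A", "C", "G", "T"), sample(1:2, 1L),
                         replace = TRUE), collapse = "")
          } else ""
          t <- t0 + sample(0:2, 1L)
          if (t + n_del + 1L > n || !same_exon(tx, t, t + n_del + 1L)) return(NULL)
          if (!reserve(tx$transcript_id, t - 1L, t + n_del + 2L)) return(NULL)
          v <- tx_indel_to_variant(tx, fasta, t, n_del, ins)
          edit <- list(tstart = t + 1L, tend = t + n_del, repl = ins)
          vclass <- if (n_del == 0L) "insertion" else "deletion"
        } else if (kind == "inframe") {
          del <- sample(c(TRUE, FALSE), 1L)
          n_del <- if (del) 3L else 0L
          ins <- if (del) "" else sample(codon_pool("full"), 1L)
          t <- t0
          if (t + n_del + 1L > n || !same_exon(tx, t, t + n_del + 1L)) return(NULL)
          if (!reserve(tx$transcript_id, t - 1L, t + n_del + 2L)) return(NULL)
          v <- tx_indel_to_variant(tx, fasta, t, n_del, ins)
          edit <- list(tstart = t + 1L, tend = t + n_del, repl = ins)
          vclass <- if (del) "deletion" else "insertion"
        } else if (kind == "strong") {
          pep <- paste(c(sample(ANCHOR_FREE_AA, 4L, replace = TRUE), "F",
                         sample(ANCHOR_FREE_AA, 3L, replace = TRUE), "L"),
                       collapse = "")
          wt_aa <- naive_translate(tx$cds_seq)
          if (grepl(pep, wt_aa, fixed = TRUE)) return(NULL)
          ins <- peptide_to_nt(pep)
          t <- t0 - 1L                # insert at the codon boundary before codon j
          if (!same_exon(tx, t, t + 1L)) return(NULL)
          if (!reserve(tx$transcript_id, t - 1L, t + 2L)) return(NULL)
          v <- tx_indel_to_variant(tx, fasta, t, 0L, ins)
          edit <- list(tstart = t + 1L, tend = t, repl = ins)
          vclass <- "insertion"
          attr(edit, "strong_peptide") <- pep
        } else stopf("unknown kind %s", kind)
        list(tx = tx, v = v, edit = edit, vclass = vclass, kind = kind)
      }, what = kind)
    }

    kinds <- c(rep("missense", n_missense), rep("synonymous", n_synonymous),
               rep("frameshift", n_frameshift), rep("inframe", n_inframe))
    design_n <- c(shared = 0L, unique_b = 0L)
    if (!is.null(strong_design)) {
      design_n <- c(shared = as.integer(strong_design$shared %||% 0),
                    unique_b = as.integer(strong_design$unique_b %||% 0))
      kinds <- c(kinds, rep("strong_shared", design_n["shared"]),
                 rep("strong_unique_b", design_n["unique_b"]))
    }
    gkinds <- rep("germline", n_germline)

    strong_peps <- character(0)
    rows <- list()
    for (kind in c(kinds, gkinds)) {
      base_kind <- sub("^strong_.*$", "strong", kind)
      p <- plant_one(base_kind)
      if (base_kind == "strong") {
        # redraw on the (vanishingly unlikely) duplicate designed peptide
        while (attr(p$edit, "strong_peptide") %in% strong_peps) {
          p <- plant_one(base_kind)
        }
        strong_peps <- c(strong_peps, attr(p$edit, "strong_peptide"))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = p$v$chrom, pos = p$v$pos, ref = p$v$ref, alt = p$v$alt,
        vclass = p$vclass, transcript_id = p$tx$transcript_id,
        gene_id = p$tx$gene_id, kind = kind,
        tstart = p$edit$tstart, tend = p$edit$tend, repl = p$edit$repl,
        strong_peptide = if (base_kind == "strong")
          attr(p$edit, "strong_peptide") else NA_character_,
        stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
    planted$germline <- planted$kind == "germline"
    somatic <- which(!planted$germline)

    # membership: B is a strict superset of A's somatic variants
    planted$in_a <- planted$in_b <- planted$germline
    if (!is.null(strong_design)) {
      planted$in_a[planted$kind %in% c("strong_shared")] <- TRUE
      planted$in_b[planted$kind %in% c("strong_shared", "strong_unique_b")] <- TRUE
      plain <- somatic[!planted$kind[somatic] %in%
                         c("strong_shared", "strong_unique_b")]
    } else {
      plain <- somatic
    }
    if (length(plain)) {
      n_shared <- round(shared_fraction * length(plain))
      in_a <- sample(plain, n_shared)
      planted$in_a[in_a] <- TRUE
      planted$in_b[plain] <- TRUE
    }

    # read support
    draw_reads <- function(n) pmax(rpois(n, mean_alt_reads), 5L)
    n_var <- nrow(planted)
    planted$wes_alt_a <- draw_reads(n_var)
    planted$wes_alt_b <- draw_reads(n_var)
    planted$wes_alt_n <- draw_reads(n_var)
    if (frac_low_wes > 0 && length(somatic)) {
      n_low <- round(frac_low_wes * length(somatic))
      low <- sample(somatic, n_low)
      planted$forced_low_wes <- seq_len(n_var) %in% low
      planted$wes_alt_a[low] <- sample(0:4, n_low, replace = TRUE)
      planted$wes_alt_b[low] <- planted$wes_alt_a[low]
    } else {
      planted$forced_low_wes <- FALSE
    }

    # expected peptides from the naive oracle (somatic variants only)
    expected <- lapply(somatic, function(i) {
      r <- planted[i, ]
      tx <- models[[r$transcript_id]]
      peps <- naive_expected_peptides(tx$cds_seq, tx$utr3_seq,
                                      r$tstart, r$tend, r$repl)
      if (length(peps) == 0L) return(NULL)
      data.frame(variant = paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"),
                 transcript_id = r$transcript_id, sequence = peps,
                 stringsAsFactors = FALSE)
    })
    expected <- do.call(rbind, expected)
    if (is.null(expected)) {
      expected <- data.frame(variant = character(), transcript_id = character(),
                             sequence = character(), stringsAsFactors = FALSE)
    }

    sample_df <- function(sel, reads, sample_name) {
      df <- planted[sel, c("chrom", "pos", "ref", "alt", "vclass"),
                    drop = FALSE]
      df$alt_reads <- reads[sel]
      df$sample <- rep(sample_name, nrow(df))
      rownames(df) <- NULL
      df
    }
    tumor_a <- sample_df(planted$in_a | planted$germline, planted$wes_alt_a,
                         "TUMOR_A")
    tumor_b <- sample_df(planted$in_b | planted$germline, planted$wes_alt_b,
                         "TUMOR_B")
    normal <- sample_df(planted$germline, planted$wes_alt_n, "NORMAL")

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      contigs <- setNames(nchar(fasta), names(fasta))
      paths <- list(
        tumor_a = file.path(out_dir, "tumor_a.vcf"),
        tumor_b = file.path(out_dir, "tumor_b.vcf"),
        normal = file.path(out_dir, "normal.vcf"))
      write_simple_vcf(tumor_a, paths$tumor_a, "TUMOR_A", contigs)
      write_simple_vcf(tumor_b, paths$tumor_b, "TUMOR_B", contigs)
      write_simple_vcf(normal, paths$normal, "NORMAL", contigs)
    }
    list(tumor_a = tumor_a, tumor_b = tumor_b, normal = normal,
         truth = list(planted = planted, expected_peptides = expected,
                      design = design_n),
         paths = paths)
  })
}

# All single-base substitutions of a codon matching the requested
# consequence; never creates a stop codon.
codon_variants <- function(codon, kind) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  out <- list()
  for (off in 0:2) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, off + 1L, off + 1L))) {
      new <- codon
      substr(new, off + 1L, off + 1L) <- b
      new_aa <- gc[[new]]
      if (new_aa == "*") next
      ok <- switch(kind,
                   missense = new_aa != aa,
                   germline = new_aa != aa,
                   synonymous = new_aa == aa)
      if (ok) out[[length(out) + 1L]] <- data.frame(
        offset = off, base = b, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(), base = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Deterministic reverse translation (first codon of each amino acid in
# the standard table).
peptide_to_nt <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) names(gc)[gc == a][1], character(1)),
        collapse = "")
}

#' Simulate RNA-seq variant support and gene expression
#'
#' Genes are expressed with probability `expressed_fraction`; variants in
#' expressed genes appear in the RNA call set with altered-read counts
#' drawn from Binomial(`depth`, VAF 0.5), while variants in unexpressed
#' genes are absent from the RNA VCFs and their genes get TPM 0.
#' Expressed genes get TPM from a log-normal distribution. A
#' configurable subset of expressed variants is forced to 1-2 altered
#' reads to exercise the >= 3 validation threshold.
#'
#' @param seed Integer seed.
#' @param planted Result of [plant_variants()].
#' @param txs Transcriptome from [generate_transcriptome()].
#' @param expressed_fraction Probability a gene is expressed.
#' @param depth RNA read depth at each variant site.
#' @param frac_low_rna Fraction of expressed somatic variants forced to
#'   1-2 RNA altered reads.
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters for expressed
#'   genes.
#' @param out_dir If non-NULL, write `rna_a.vcf`, `rna_b.vcf`,
#'   `expression.tsv` there.
#' @return List with `rna_a`, `rna_b` (RNA variant data frames),
#'   `expression` (named TPM vector), `expressed_genes`, `paths`.
#' @export
simulate_rna_support <- function(seed, planted, txs, expressed_fraction = 0.8,
                                 depth = 100, frac_low_rna = 0,
                                 tpm_meanlog = 2, tpm_sdlog = 1,
                                 out_dir = NULL) {
  pl <- planted$truth$planted
  genes <- unname(vapply(txs$txs, `[[`, character(1), "gene_id"))
  withr::with_seed(seed, {
    expressed <- genes[runif(length(genes)) < expressed_fraction]
    tpm <- setNames(rep(0, length(genes)), genes)
    tpm[expressed] <- rlnorm(length(expressed), tpm_meanlog, tpm_sdlog)

    somatic <- which(!pl$germline)
    var_expressed <- pl$gene_id %in% expressed
    rna_reads <- pmax(rbinom(nrow(pl), depth, 0.5), 3L)
    forced_low <- rep(FALSE, nrow(pl))
    low_pool <- somatic[var_expressed[somatic]]
    if (frac_low_rna > 0 && length(low_pool)) {
      n_low <- round(frac_low_rna * length(low_pool))
      low <- sample(low_pool, n_low)
      rna_reads[low] <- sample(1:2, n_low, replace = TRUE)
      forced_low[low] <- TRUE
    }

    rna_df <- function(sel, sample_name) {
      df <- pl[sel & var_expressed, c("chrom", "pos", "ref", "alt", "vclass"),
               drop = FALSE]
      df$alt_reads <- rna_reads[sel & var_expressed]
      df$sample <- rep(sample_name, nrow(df))
      rownames(df) <- NULL
      df
    }
    rna_a <- rna_df(pl$in_a | pl$germline, "RNA_A")
    rna_b <- rna_df(pl$in_b | pl$germline, "RNA_B")

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      contigs <- setNames(nchar(txs$fasta), names(txs$fasta))
      paths <- list(rna_a = file.path(out_dir, "rna_a.vcf"),
                    rna_b = file.path(out_dir, "rna_b.vcf"),
                    expression = file.path(out_dir, "expression.tsv"))
      write_simple_vcf(rna_a, paths$rna_a, "RNA_A", contigs)
      write_simple_vcf(rna_b, paths$rna_b, "RNA_B", contigs)
      con <- file(paths$expression, open = "wb")
      writeLines(c("gene_id\tTPM",
                   sprintf("%s\t%s", genes, fmt_num(unname(tpm)))),
                 con, sep = "\n")
      close(con)
    }
    list(rna_a = rna_a, rna_b = rna_b, expression = tpm,
         expressed_genes = expressed, var_expressed = var_expressed,
         forced_low_rna = forced_low, paths = paths)
  })
}

#' Simulate a cohort with a latent cDC1 factor and survival
#'
#' Each sample carries a latent factor `f ~ N(0,1)`. Every cDC1- and CD8
#' effector-signature gene is generated as `beta * f + noise` and then
#' re-standardized to cohort z-scores (mean 0, sd 1 per gene), so the
#' two signature scores are positively coupled through `f` when
#' `beta > 0`. TMB is log-normal and independent of `f`. Survival times
#' are exponential with the baseline hazard multiplied by `hr` for the
#' planted low-factor group (`f < 0`), with independent uniform
#' censoring.
#'
#' @param seed Integer seed.
#' @param n Cohort size (>= 100).
#' @param beta Coupling between the latent factor and signature genes.
#' @param hr Hazard ratio of the low-factor group versus the rest.
#' @param base_hazard Baseline exponential hazard per month (default
#'   gives a 50-month median survival in the reference group).
#' @param censor_max Upper bound (months) of the uniform censoring time.
#' @param out_path If non-NULL, write the cohort TSV there.
#' @return List with `cohort` (data frame: `sample_id`, `tmb`,
#'   `time_months`, `event`, one column per gene) and `truth` (latent
#'   factor and parameters).
#' @export
simulate_cohort <- function(seed, n = 500, beta = 1, hr = 2,
                            base_hazard = log(2) / 50, censor_max = 120,
                            out_path = NULL) {
  stopifnot(n >= 100)
  genes <- c(signature_def("cdc1")$genes, signature_def("cd8_effector")$genes)
  withr::with_seed(seed, {
    f <- rnorm(n)
    z <- vapply(genes, function(g) {
      raw <- beta * f + rnorm(n)
      as.numeric(scale(raw))
    }, numeric(n))
    colnames(z) <- genes
    tmb <- rlnorm(n, meanlog = log(8), sdlog = 0.8)
    hazard <- base_hazard * ifelse(f < 0, hr, 1)
    t_event <- rexp(n, hazard)
    t_cens <- runif(n, 0, censor_max)
    cohort <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                         tmb = tmb,
                         time_months = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(z))
    if (!is.null(out_path)) {
      con <- file(out_path, open = "wb")
      header <- paste(names(cohort), collapse = "\t")
      body <- vapply(seq_len(n), function(i) {
        paste(c(cohort$sample_id[i],
                fmt_num(as.numeric(cohort[i, -1]))), collapse = "\t")
      }, character(1))
      writeLines(c(header, body), con, sep = "\n")
      close(con)
    }
    list(cohort = cohort,
         truth = list(f = f, low_group = f < 0,
                      params = list(n = n, beta = beta, hr = hr)))
  })
}
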