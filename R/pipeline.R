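# End-to-end orchestration: read inputs, subtract germline, apply the
# WES support filter, enumerate and bind peptides, validate on RNA,
# attach TPM, build the two catalogs and compare them. A JSON run
# manifest records the configuration, input checksums and per-stage
# counts; outputs are deterministic given inputs + configuration.

#' Build a pipeline configuration
#'
#' Defaults are the study's stated parameters: WES support >= 5 altered
#' reads, RNA support >= 3, percent rank <= 0.5, peptide lengths 8-11,
#' alleles H2-Kb and H2-Db.
#'
#' @param fasta,gtf Reference sequences and transcript annotation.
#' @param wes_a,wes_b,normal Tumour (lines A, B) and matched-normal WES
#'   VCFs.
#' @param rna_a,rna_b RNA-seq variant-call VCFs per line.
#' @param expression Gene-level expression TSV (`gene_id`, `TPM`).
#' @param sample_a,sample_b,sample_normal,sample_rna_a,sample_rna_b VCF
#'   sample names.
#' @param min_wes_alt,min_rna_alt,rank_max Filter thresholds.
#' @param lengths Peptide window lengths. Values outside 8-11 are
#'   accepted (up to 1-15) with a warning.
#' @param alleles MHC class I alleles for the predictor.
#' @param predictor `"toy"` for the built-in deterministic predictor, or
#'   `"netmhc-table"` to read predictions from `netmhc_table`.
#' @param netmhc_table Path to a NetMHC-style prediction table covering
#'   all peptides (required for `predictor = "netmhc-table"`).
#' @param out_dir Output directory (catalogs + manifest); `NULL` for
#'   in-memory results only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, gtf, wes_a, wes_b, normal, rna_a, rna_b,
                            expression,
                            sample_a = "TUMOR_A", sample_b = "TUMOR_B",
                            sample_normal = "NORMAL",
                            sample_rna_a = "RNA_A", sample_rna_b = "RNA_B",
                            min_wes_alt = 5L, min_rna_alt = 3L,
                            rank_max = 0.5, lengths = 8:11,
                            alleles = c("H2-Kb", "H2-Db"),
                            predictor = c("toy", "netmhc-table"),
                            netmhc_table = NULL, out_dir = NULL) {
  predictor <- match.arg(predictor)
  stopifnot(min_wes_alt >= 0, min_rna_alt >= 0, rank_max > 0)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L | lengths > 15L)) {
    stopf("peptide lengths must lie in [1, 15]")
  }
  if (any(lengths < 8L | lengths > 11L)) {
    warnf("peptide lengths outside the standard 8-11 window: %s",
          paste(setdiff(lengths, 8:11), collapse = ", "))
  }
  if (predictor == "netmhc-table" && is.null(netmhc_table)) {
    stopf("predictor 'netmhc-table' requires netmhc_table")
  }
  structure(list(
    fasta = fasta, gtf = gtf, wes_a = wes_a, wes_b = wes_b, normal = normal,
    rna_a = rna_a, rna_b = rna_b, expression = expression,
    sample_a = sample_a, sample_b = sample_b, sample_normal = sample_normal,
    sample_rna_a = sample_rna_a, sample_rna_b = sample_rna_b,
    min_wes_alt = as.integer(min_wes_alt),
    min_rna_alt = as.integer(min_rna_alt),
    rank_max = rank_max, lengths = lengths,
    alleles = normalize_allele(alleles), predictor = predictor,
    netmhc_table = netmhc_table, out_dir = out_dir), class = "pipeline_config")
}

#' Run the full neoantigen pipeline for two cell lines
#'
#' Stage order: read inputs, germline subtraction, WES support filter,
#' variant application and peptide enumeration, binding prediction and
#' strong-binder filter, RNA validation, TPM attachment, catalog
#' construction and shared/unique classification. Any stage error aborts
#' with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `catalog_a`, `catalog_b`, `comparison` (from
#'   [classify_shared_unique()]), `manifest` (per-stage counts, config,
#'   input checksums) and the written `paths` when `out_dir` was set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  fasta <- stage("read_fasta", read_fasta(cfg$fasta))
  txs <- stage("read_gtf", read_gtf_cds(cfg$gtf, fasta))
  tx2gene <- vapply(txs, `[[`, character(1), "gene_id")
  expr_tab <- stage("read_expression", read_expression(cfg$expression))
  wes_a <- stage("read_vcf", read_vcf(cfg$wes_a, cfg$sample_a))
  wes_b <- stage("read_vcf", read_vcf(cfg$wes_b, cfg$sample_b))
  normal <- stage("read_vcf", read_vcf(cfg$normal, cfg$sample_normal))
  rna_a <- stage("read_vcf", read_vcf(cfg$rna_a, cfg$sample_rna_a))
  rna_b <- stage("read_vcf", read_vcf(cfg$rna_b, cfg$sample_rna_b))
  counts$input_variants <- c(A = nrow(wes_a), B = nrow(wes_b))

  run_line <- function(wes, rna, line) {
    som <- stage("subtract_germline", subtract_germline(wes, normal))
    counts[[paste0("somatic_", line)]] <<- nrow(som)
    sup <- stage("filter_wes_support",
                 filter_wes_support(som, cfg$min_wes_alt))
    counts[[paste0("wes_supported_", line)]] <<- nrow(sup)
    ann <- stage("annotate_transcripts", annotate_transcripts(sup, txs))
    peps <- stage("enumerate_peptides", {
      out <- lapply(seq_len(nrow(ann)), function(i) {
        v <- ann[i, , drop = FALSE]
        mp <- apply_variant(txs[[v$transcript_id]],
                            v[, c("chrom", "pos", "ref", "alt", "vclass",
                                  "alt_reads", "sample")])
        if (is.null(mp)) return(NULL)
        enumerate_neoepitopes(mp, lengths = cfg$lengths)
      })
      out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
      if (is.null(out)) out <- enumerate_empty() else out
    })
    counts[[paste0("peptides_", line)]] <<- nrow(peps)
    bindings <- stage("binding", {
      if (cfg$predictor == "toy") {
        predict_toy_all(peps$sequence, cfg$alleles)
      } else {
        parse_netmhc_table(cfg$netmhc_table)
      }
    })
    strong <- stage("strong_binders",
                    filter_strong_binders(bindings, cfg$rank_max))
    counts[[paste0("strong_peptides_", line)]] <<-
      length(intersect(unique(strong$peptide), peps$sequence))
    ev <- stage("validate_rna", validate_rna(sup, rna, cfg$min_rna_alt))
    counts[[paste0("rna_validated_", line)]] <<- nrow(ev)
    ev <- stage("annotate_transcripts", annotate_transcripts(ev, txs))
    ev <- stage("attach_tpm", attach_tpm(ev, expr_tab, tx2gene))
    cat <- stage("build_catalog",
                 build_catalog(ev, peps, bindings, line, cfg$rank_max))
    counts[[paste0("catalog_", line)]] <<- nrow(cat)
    cat
  }

  catalog_a <- run_line(wes_a, rna_a, "A")
  catalog_b <- run_line(wes_b, rna_b, "B")
  comparison <- stage("classify", classify_shared_unique(catalog_a, catalog_b))
  classified <- rbind(comparison$shared, comparison$unique_A,
                      comparison$unique_B)
  counts$venn <- as.list(comparison$counts)

  inputs <- c(fasta = cfg$fasta, gtf = cfg$gtf, wes_a = cfg$wes_a,
              wes_b = cfg$wes_b, normal = cfg$normal, rna_a = cfg$rna_a,
              rna_b = cfg$rna_b, expression = cfg$expression)
  md5 <- unname(tools::md5sum(unname(inputs)))  # keyed by role, not path
  manifest <- list(
    tool = "neoforge",
    version = as.character(utils::packageVersion("neoforge")),
    config = cfg[c("min_wes_alt", "min_rna_alt", "rank_max", "lengths",
                   "alleles", "predictor")],
    input_md5 = as.list(setNames(md5, names(inputs))),
    stage_counts = counts)

  paths <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      catalog_a = file.path(cfg$out_dir, "catalog_A.tsv"),
      catalog_b = file.path(cfg$out_dir, "catalog_B.tsv"),
      classified = file.path(cfg$out_dir, "catalog_classified.tsv"),
      manifest = file.path(cfg$out_dir, "manifest.json"))
    write_catalog(catalog_a, paths$catalog_a)
    write_catalog(catalog_b, paths$catalog_b)
    write_catalog(classified, paths$classified)
    json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
    con <- file(paths$manifest, open = "wb")
    writeLines(json, con, sep = "\n")
    close(con)
  }

  list(catalog_a = catalog_a, catalog_b = catalog_b, comparison = comparison,
       classified = classified, manifest = manifest, paths = paths)
}

enumerate_empty <- function() {
  data.frame(sequence = character(), length = integer(),
             window_start = integer(), n_mut_residues = integer(),
             transcript_id = character(), gene_id = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character(), stringsAsFactors = FALSE)
}
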