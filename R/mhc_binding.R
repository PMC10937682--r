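# MHC class I binding predictions: a parser for NetMHC-4.0-style tabular
# output, a deterministic motif-based toy predictor (for tests and for
# running the pipeline without NetMHC), and the strong-binder filter on
# percent rank. The neural-network affinity models themselves are
# interfaced, never re-implemented.

TOY_ALLELES <- c("H2-Kb", "H2-Db")

#' Normalize an MHC allele name
#'
#' NetMHC output spells mouse alleles inconsistently across versions
#' ("H-2-Kb", "H2-Kb", "h2kb"). Hyphens, underscores and case are
#' stripped before matching; the two C57BL/6 haplotypes unify to
#' `"H2-Kb"` / `"H2-Db"`. Unrecognized alleles are returned unchanged.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of normalized names.
#' @export
normalize_allele <- function(allele) {
  key <- toupper(gsub("[-_ ]", "", allele))
  canon <- c(H2KB = "H2-Kb", H2DB = "H2-Db")
  out <- unname(canon[key])
  ifelse(is.na(out), allele, out)
}

#' Parse a NetMHC-style whitespace-delimited prediction table
#'
#' Banner/comment lines starting with `#` or `-` and blank lines are
#' skipped. The header row must name a peptide column (`Peptide`), an
#' allele column (`MHC` or `Allele`), a percent-rank column (`%Rank`,
#' `Rank` or `%Rank_EL`) and an affinity column (`Aff(nM)`, `Affinity`
#' or `Aff`); both NetMHC 4.0 and netMHCpan 4.0 layouts are accepted.
#'
#' @param path Path to the table.
#' @return Data frame of binding predictions with columns `peptide`,
#'   `allele` (normalized), `percent_rank`, `ic50_nm`.
#' @export
parse_netmhc_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|-)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stopf("no data rows in %s", path)
  toks <- strsplit(trimws(lines), "\\s+")
  header <- toks[[1]]
  find_col <- function(cands) {
    hit <- which(tolower(header) %in% tolower(cands))
    if (length(hit)) hit[1] else NA_integer_
  }
  cols <- c(peptide = find_col("Peptide"),
            allele = find_col(c("MHC", "Allele", "HLA")),
            rank = find_col(c("%Rank", "Rank", "%Rank_EL", "Rank_EL")),
            aff = find_col(c("Aff(nM)", "Affinity", "Aff", "Affinity(nM)", "ic50")))
  if (anyNA(cols)) {
    stopf("missing required column(s) %s in %s; found columns: %s",
          paste(names(cols)[is.na(cols)], collapse = ", "), path,
          paste(header, collapse = ", "))
  }
  rows <- toks[-1]
  lineno <- lineno[-1]
  parse_num <- function(x, i, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stopf("unparseable %s value '%s' at line %d of %s",
                        what, x, lineno[i], path)
    v
  }
  out <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (length(r) < max(cols)) {
      stopf("truncated row at line %d of %s", lineno[i], path)
    }
    data.frame(peptide = r[cols["peptide"]],
               allele = normalize_allele(r[cols["allele"]]),
               percent_rank = parse_num(r[cols["rank"]], i, "rank"),
               ic50_nm = parse_num(r[cols["aff"]], i, "affinity"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  validate_bindings(out)
  out
}

validate_bindings <- function(preds) {
  stopifnot(all(c("peptide", "allele", "percent_rank", "ic50_nm") %in%
                  names(preds)))
  if (any(preds$percent_rank <= 0) || any(preds$ic50_nm <= 0)) {
    stopf("percent_rank and ic50_nm must be positive")
  }
  invisible(preds)
}

#' Deterministic toy MHC-I binding predictor
#'
#' A pure, motif-based stand-in used to exercise the pipeline without
#' NetMHC. It is explicitly non-biological: real runs should parse real
#' predictor output with [parse_netmhc_table()]. Anchor rules: `H2-Kb`
#' requires F/Y at peptide position 5 and L/M/I/V at the C-terminus;
#' `H2-Db` requires N at position 5 and M/I/L/V at the C-terminus. Two
#' matched anchors give rank 0.1 / 50 nM, one gives 1.0 / 500 nM, none
#' gives 50.0 / 5000 nM.
#'
#' @param peptide Character vector of peptides (length 8-11 each).
#' @param allele Allele name (recycled), one of `"H2-Kb"`, `"H2-Db"`.
#' @return Data frame of binding predictions (same columns as
#'   [parse_netmhc_table()]).
#' @export
predict_toy <- function(peptide, allele) {
  allele <- normalize_allele(allele)
  if (length(allele) == 1L) allele <- rep(allele, length(peptide))
  stopifnot(length(allele) == length(peptide))
  if (!all(allele %in% TOY_ALLELES)) {
    stopf("unknown allele '%s' (toy predictor knows: %s)",
          setdiff(allele, TOY_ALLELES)[1], paste(TOY_ALLELES, collapse = ", "))
  }
  len <- nchar(peptide)
  if (any(len < 8L | len > 11L)) {
    stopf("toy predictor requires peptide length 8-11 (got %d for '%s')",
          len[which(len < 8 | len > 11)[1]], peptide[which(len < 8 | len > 11)[1]])
  }
  p5 <- substr(peptide, 5L, 5L)
  cterm <- substr(peptide, len, len)
  n_anchor <- ifelse(allele == "H2-Kb", p5 %in% c("F", "Y"), p5 == "N") +
    (cterm %in% c("L", "M", "I", "V"))
  data.frame(peptide = peptide, allele = allele,
             percent_rank = c(50, 1, 0.1)[n_anchor + 1L],
             ic50_nm = c(5000, 500, 50)[n_anchor + 1L],
             stringsAsFactors = FALSE)
}

#' Predict binding of each peptide against every allele
#'
#' Convenience wrapper building the full (peptide x allele) prediction
#' table with the toy predictor.
#'
#' @param peptides Character vector of peptide sequences.
#' @param alleles Character vector of alleles (default both C57BL/6
#'   class I haplotypes).
#' @return Data frame of binding predictions, one row per combination.
#' @export
predict_toy_all <- function(peptides, alleles = TOY_ALLELES) {
  peptides <- unique(peptides)
  if (length(peptides) == 0L) {
    return(data.frame(peptide = character(), allele = character(),
                      percent_rank = numeric(), ic50_nm = numeric(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  predict_toy(grid$peptide, grid$allele)
}

#' Keep strong binders (percent rank at or below a threshold)
#'
#' The threshold is inclusive: rank exactly equal to `rank_max` is kept.
#'
#' @param preds Binding prediction data frame.
#' @param rank_max Maximum percent rank (default 0.5, the conventional
#'   strong-binder cutoff).
#' @return The subset of `preds` passing the filter.
#' @export
filter_strong_binders <- function(preds, rank_max = 0.5) {
  stopifnot(rank_max > 0)
  validate_bindings(preds)
  out <- preds[preds$percent_rank <= rank_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best (minimum percent rank) prediction per peptide; ties broken by
# allele name for determinism.
best_binding <- function(preds) {
  if (nrow(preds) == 0L) return(preds)
  preds <- preds[order(preds$peptide, preds$percent_rank, preds$allele), ,
                 drop = FALSE]
  out <- preds[!duplicated(preds$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}
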