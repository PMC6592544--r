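# Clonotype table input/output, validation, collapsing and VJ partitioning.
#
# A repertoire is the standard unit of RepSeq analysis here: a table of unique
# nucleotide-level TCR rearrangements (clonotypes), each with a CDR3 nucleotide
# and amino-acid sequence, V and J gene calls and a read count.

#' Construct a repertoire object
#'
#' A `tcr_repertoire` wraps a clonotype table (a `data.table` with columns
#' `cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`, `read_count`, `frequency`)
#' together with a sample identifier and provenance counters (rows read,
#' excluded, collapsed).
#'
#' @param clonotypes data.frame with the columns above (`frequency` optional).
#' @param sample_id sample label.
#' @param provenance named list of free-form metadata.
#' @param validate run invariant checks (translation consistency, canonical
#'   amino acids, positive counts)?
#' @param on_invalid `"drop"` (exclude offending rows, count them) or
#'   `"error"`.
#' @return object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(clonotypes, sample_id = "sample",
                           provenance = list(), validate = TRUE,
                           on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  cl <- data.table::as.data.table(clonotypes)
  needed <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "read_count")
  miss <- setdiff(needed, names(cl))
  if (length(miss)) stopf("clonotype table lacks column(s): %s", paste(miss, collapse = ", "))
  cl[, cdr3_nt := toupper(as.character(cdr3_nt))]
  cl[, cdr3_aa := toupper(as.character(cdr3_aa))]
  cl[, read_count := as.integer(read_count)]
  n_in <- nrow(cl)
  excluded <- list(noncanonical_aa = 0L, translation_mismatch = 0L, bad_count = 0L)
  if (validate && n_in) {
    bad_count <- is.na(cl$read_count) | cl$read_count < 1L
    # translation check only where the nt sequence is in frame
    tr <- translate_cdr3(cl$cdr3_nt)
    mism <- !is.na(tr) & tr != cl$cdr3_aa
    noncanon <- !is_canonical_aa(cl$cdr3_aa)
    bad <- bad_count | mism | noncanon
    if (any(bad) && on_invalid == "error") {
      stopf("%d invalid clonotype row(s) (non-canonical CDR3aa, translation mismatch, or read_count < 1)",
            sum(bad))
    }
    excluded$bad_count <- sum(bad_count)
    excluded$translation_mismatch <- sum(mism & !bad_count)
    excluded$noncanonical_aa <- sum(noncanon & !bad_count & !mism)
    cl <- cl[!bad]
  }
  if (!"frequency" %in% names(cl) || all(is.na(cl$frequency))) {
    tot <- sum(cl$read_count)
    cl[, frequency := if (tot > 0) read_count / tot else numeric(nrow(cl))]
  } else {
    cl[, frequency := as.numeric(frequency)]
    if (nrow(cl) && sum(cl$frequency, na.rm = TRUE) > 1 + 1e-6) {
      warning("clonotype frequencies sum to more than 1", call. = FALSE)
    }
  }
  data.table::setcolorder(cl, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
                                "read_count", "frequency"))
  structure(list(clonotypes = cl, sample_id = sample_id,
                 provenance = utils::modifyList(list(rows_in = n_in, excluded = excluded),
                                                provenance)),
            class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> sample '%s': %d clonotypes, %d reads\n",
              x$sample_id, nrow(x$clonotypes), sum(x$clonotypes$read_count)))
  ex <- x$provenance$excluded
  if (!is.null(ex) && sum(unlist(ex)) > 0) {
    cat(sprintf("  excluded rows: %s\n",
                paste(sprintf("%s=%d", names(ex), unlist(ex)), collapse = ", ")))
  }
  invisible(x)
}

# Column-name dialects for common clonotype-table exports. Values are the
# column headers expected in the file for each canonical field.
DIALECTS <- list(
  vdjtools = c(read_count = "count", frequency = "freq", cdr3_nt = "cdr3nt",
               cdr3_aa = "cdr3aa", v_gene = "v", j_gene = "j"),
  mixcr = c(read_count = "cloneCount", frequency = "cloneFraction",
            cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
            v_gene = "allVHitsWithScore", j_gene = "allJHitsWithScore")
)

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table (VDJtools-style by default) into a
#' validated [tcr_repertoire]. Rows whose CDR3 amino-acid sequence contains
#' non-canonical letters (stop `*`, `X`, `_`), disagrees with the translation
#' of an in-frame CDR3 nucleotide sequence, or has a read count below 1 are
#' excluded from analysis; exclusion counts are kept in the repertoire's
#' provenance.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect `"vdjtools"`, `"mixcr"`, or a named character vector mapping
#'   canonical fields (`read_count`, `cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`,
#'   optionally `frequency`) to column names in the file.
#' @param sample_id sample label; defaults to the file name.
#' @param strip_alleles drop IMGT allele suffixes (`*01`) from V/J calls so VJ
#'   classes are gene-level.
#' @param verbose print a per-file summary?
#' @return a [tcr_repertoire].
#' @export
read_clonotype_table <- function(path, dialect = "vdjtools",
                                 sample_id = basename(path),
                                 strip_alleles = TRUE, verbose = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("empty input file: %s", path)
  if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(DIALECTS)) {
      stopf("unknown dialect '%s' (available: %s)", dialect,
            paste(names(DIALECTS), collapse = ", "))
    }
    dialect <- DIALECTS[[dialect]]
  }
  tab <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                      colClasses = list(character = unname(dialect[c("cdr3_nt", "cdr3_aa")]))),
    error = function(e) stopf("cannot read '%s': %s", path, conditionMessage(e)))
  if (nrow(tab) == 0L && ncol(tab) == 0L) stopf("empty input file: %s", path)
  required <- c("read_count", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(tab)) {
      stopf("required column '%s' (field %s) missing from %s",
            if (is.null(col)) field else col, field, path)
    }
  }
  out <- data.table::data.table(
    cdr3_nt = tab[[dialect[["cdr3_nt"]]]],
    cdr3_aa = tab[[dialect[["cdr3_aa"]]]],
    v_gene = as.character(tab[[dialect[["v_gene"]]]]),
    j_gene = as.character(tab[[dialect[["j_gene"]]]]),
    read_count = tab[[dialect[["read_count"]]]]
  )
  if (!is.na(dialect["frequency"]) && dialect[["frequency"]] %in% names(tab)) {
    out[, frequency := as.numeric(tab[[dialect[["frequency"]]]])]
  }
  if (strip_alleles) {
    out[, v_gene := strip_allele(v_gene)]
    out[, j_gene := strip_allele(j_gene)]
  }
  rep <- tcr_repertoire(out, sample_id = sample_id,
                        provenance = list(path = path))
  if (verbose) {
    message(sprintf("%s: %d rows read, %d retained, %d excluded",
                    path, rep$provenance$rows_in, nrow(rep$clonotypes),
                    rep$provenance$rows_in - nrow(rep$clonotypes)))
  }
  rep
}

#' Write a clonotype table
#'
#' Writes the repertoire's clonotype table back to VDJtools-dialect TSV
#' (columns `count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `j`).
#'
#' @param rep a [tcr_repertoire].
#' @param path output file path.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  out <- data.table::data.table(count = cl$read_count, freq = cl$frequency,
                                cdr3nt = cl$cdr3_nt, cdr3aa = cl$cdr3_aa,
                                v = cl$v_gene, j = cl$j_gene)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Collapse germline sequencing errors
#'
#' Merges clonotypes with identical CDR3 nucleotide sequence and V/J calls
#' (residual duplicates typically caused by sequencing errors in germline
#' regions upstream of clonotype calling), summing their read counts.
#' Idempotent; the output is unique on (cdr3_nt, v_gene, j_gene) and sorted
#' canonically.
#'
#' @param rep a [tcr_repertoire].
#' @return a collapsed [tcr_repertoire].
#' @export
collapse_clonotypes <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  n_before <- nrow(cl)
  merged <- cl[, .(cdr3_aa = cdr3_aa[1L], read_count = sum(read_count),
                   frequency = sum(frequency)),
               by = .(cdr3_nt, v_gene, j_gene)]
  data.table::setorder(merged, v_gene, j_gene, cdr3_nt)
  data.table::setcolorder(merged, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
                                    "read_count", "frequency"))
  prov <- rep$provenance
  prov$rows_collapsed <- (prov$rows_collapsed %||% 0L) + (n_before - nrow(merged))
  out <- rep
  out$clonotypes <- merged
  out$provenance <- prov
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a repertoire into VJ classes
#'
#' The enrichment statistics are computed within classes of clonotypes sharing
#' the same V and J gene call. Every clonotype belongs to exactly one class;
#' each class records `n`, its number of unique nucleotide clonotypes.
#'
#' @param rep a collapsed [tcr_repertoire].
#' @return named list of `vj_class` objects (list with `v_gene`, `j_gene`,
#'   `n`, and `clonotypes` data.table), keyed `"V|J"`.
#' @export
partition_vj <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  if (nrow(cl) == 0L) return(structure(list(), names = character(0)))
  split_cl <- split(cl, paste(cl$v_gene, cl$j_gene, sep = "|"))
  out <- lapply(split_cl, function(m) {
    structure(list(v_gene = m$v_gene[1L], j_gene = m$j_gene[1L],
                   n = nrow(m), clonotypes = m),
              class = "vj_class")
  })
  out[order(names(out))]
}
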