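#' Construct an expression matrix container
#'
#' A thin validated container for genes x samples abundance values with a
#' unit tag.  All downstream analyses take this structure.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors; taken from `dimnames(values)`
#'   when omitted.
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `unit` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              unit = c("LOG2", "FPKM", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  if (unit == "TPM") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6))
      stop("TPM columns must sum to 1e6; offending sample: ",
           sample_ids[which.max(abs(cs - 1e6))])
  }
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

expr_unit <- function(m) attr(m, "unit")

#' Read a genes x samples expression TSV
#'
#' First column gene ids, header row sample ids.  Duplicate gene rows are
#' collapsed by arithmetic mean (a message reports how many).
#'
#' @param path TSV file path.
#' @param unit_hint unit of the stored values (`"LOG2"`, `"FPKM"`, `"TPM"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, unit_hint = c("LOG2", "FPKM", "TPM")) {
  unit_hint <- match.arg(unit_hint)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("malformed expression file: need gene column plus >= 1 sample")
  ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric values in sample column '", sample_ids[bad], "'")
  }
  if (anyDuplicated(ids)) {
    ndup <- sum(duplicated(ids))
    vals <- rowsum(vals, group = ids, reorder = FALSE) /
      as.vector(table(ids)[unique(ids)])
    ids <- rownames(vals)
    message(ndup, " duplicate gene row(s) collapsed by mean")
  }
  expression_matrix(vals, ids, sample_ids, unit = unit_hint)
}

#' Write an expression matrix as TSV
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM values to TPM
#'
#' TPM_ij = FPKM_ij / sum_i(FPKM_ij) * 1e6, so each sample column sums to
#' one million.
#'
#' @param m an [expression_matrix()] with unit `"FPKM"` and nonnegative values.
#' @return The matrix rescaled per sample, unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(m) {
  if (expr_unit(m) != "FPKM") stop("fpkm_to_tpm expects unit FPKM, got ", expr_unit(m))
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("zero-sum expression column for sample: ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  expression_matrix(sweep(unclass(m), 2L, cs, "/") * 1e6,
                    rownames(m), colnames(m), unit = "TPM")
}

#' Log2(x + 1) transform of linear-scale expression
#'
#' Applied exactly once at pipeline entry when the unit is FPKM or TPM;
#' LOG2 input passes through unchanged.
#'
#' @param m an [expression_matrix()].
#' @return The matrix on log2 scale, unit `"LOG2"`.
#' @export
log2_transform <- function(m) {
  if (expr_unit(m) == "LOG2") return(m)
  if (any(m < 0)) stop("linear-scale expression must be nonnegative")
  expression_matrix(log2(unclass(m) + 1), rownames(m), colnames(m), unit = "LOG2")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @return A named list of character vectors with a `description` attribute
#'   (class `gene_sets`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names))
    stop("duplicate gene-set name: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  class(sets) <- "gene_sets"
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (defaults to the name).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- names(sets)
  lines <- mapply(function(nm, d, mem) paste(c(nm, d, mem), collapse = "\t"),
                  names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-subset mutation table
#'
#' Requires columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`; extra columns are ignored.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `gene_symbol`, `variant_class`.
#' @export
read_maf <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("MAF file missing required column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(tab$Tumor_Sample_Barcode),
                    gene_symbol = as.character(tab$Hugo_Symbol),
                    variant_class = as.character(tab$Variant_Classification),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sample_id)) || any(!nzchar(out$gene_symbol)))
    stop("MAF records with empty sample or gene identifier")
  out
}

#' Read a gene x sample CNV call matrix
#'
#' GISTIC-style integer codes in {-2,-1,0,1,2}.
#'
#' @param path TSV path, first column gene ids, header sample ids.
#' @return integer matrix with dimnames.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(calls) <- as.character(tab[[1L]])
  if (!all(calls %in% -2:2))
    stop("CNV calls outside {-2,-1,0,1,2}; first bad value: ",
         calls[which(!(calls %in% -2:2))[1L]])
  storage.mode(calls) <- "integer"
  calls
}

#' Read a clinical table
#'
#' Requires `sample_id`, `os_time`, `os_event`; optional `age`, `gender`,
#' `stage` (ordinal I-IV).  Samples with missing survival time or event are
#' dropped with a message.
#'
#' @param path TSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("clinical file missing column(s): ",
                         paste(miss, collapse = ", "))
  drop <- is.na(tab$os_time) | is.na(tab$os_event)
  if (any(drop)) {
    message(sum(drop), " sample(s) without survival information excluded")
    tab <- tab[!drop, , drop = FALSE]
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(tab$os_time < 0)) stop("negative os_time for sample: ",
                                 tab$sample_id[which(tab$os_time < 0)[1L]])
  if (!all(tab$os_event %in% c(0, 1)))
    stop("os_event outside {0,1} for sample: ",
         tab$sample_id[which(!(tab$os_event %in% c(0, 1)))[1L]])
  if ("stage" %in% colnames(tab)) {
    ok <- is.na(tab$stage) | tab$stage %in% c("I", "II", "III", "IV")
    if (!all(ok)) stop("stage must be one of I, II, III, IV")
  }
  rownames(tab) <- tab$sample_id
  tab
}

#' The 23-gene m6A regulator catalog
#'
#' Writers (methyltransferases) install the N6-methyladenosine mark,
#' erasers (demethylases) remove it, and readers (binding proteins)
#' recognise it.  The panel covers 8 writers, 13 readers and 2 erasers.
#'
#' @return data.frame with columns `symbol`, `category`, `full_name`.
#' @export
default_regulator_catalog <- function() {
  entries <- list(
    c("METTL3",    "WRITER", "Methyltransferase-like protein 3"),
    c("METTL14",   "WRITER", "Methyltransferase-like protein 14"),
    c("METTL16",   "WRITER", "Methyltransferase-like protein 16"),
    c("WTAP",      "WRITER", "Wilms tumor 1-associated protein"),
    c("VIRMA",     "WRITER", "Vir-like m6A methyltransferase associated protein"),
    c("ZC3H13",    "WRITER", "Zinc finger CCCH domain-containing protein 13"),
    c("RBM15",     "WRITER", "RNA-binding motif protein 15"),
    c("RBM15B",    "WRITER", "RNA binding motif protein 15B"),
    c("YTHDC1",    "READER", "YTH domain-containing 1"),
    c("YTHDC2",    "READER", "YTH domain-containing 2"),
    c("YTHDF1",    "READER", "YTH m6A RNA-binding protein 1"),
    c("YTHDF2",    "READER", "YTH m6A RNA-binding protein 2"),
    c("YTHDF3",    "READER", "YTH m6A RNA-binding protein 3"),
    c("HNRNPC",    "READER", "Heterogeneous nuclear ribonucleoprotein C"),
    c("FMR1",      "READER", "Fragile X mental retardation protein"),
    c("LRPPRC",    "READER", "Leucine-rich PPR-motif-containing protein"),
    c("HNRNPA2B1", "READER", "Heterogeneous nuclear ribonucleoprotein A2B1"),
    c("IGFBP1",    "READER", "Insulin-like growth factor binding protein 1"),
    c("IGFBP2",    "READER", "Insulin-like growth factor binding protein 2"),
    c("IGFBP3",    "READER", "Insulin-like growth factor binding protein 3"),
    c("RBMX",      "READER", "X-linked RNA-binding motif protein"),
    c("FTO",       "ERASER", "Fat mass and obesity-associated protein"),
    c("ALKBH5",    "ERASER", "Alk B homologue 5"))
  out <- data.frame(symbol = vapply(entries, `[[`, character(1), 1L),
                    category = vapply(entries, `[[`, character(1), 2L),
                    full_name = vapply(entries, `[[`, character(1), 3L),
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$symbol))
  out
}
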