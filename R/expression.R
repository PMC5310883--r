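# Expression TSV dialect: UTF-8, tab-separated, header row whose first
# column is `gene_id` and whose remaining columns are sample names in
# experiment order; `#`-prefixed comment lines are ignored. The mode
# (abundance vs log fold change) is always chosen by the caller, never
# inferred from the values.

#' Read a genes-by-samples expression TSV
#'
#' @param path File path.
#' @param mode \code{"abundance"} (RPKM/FPKM, values must be >= 0) or
#'   \code{"log_fold_change"} (may be negative).
#' @return An [ExpressionMatrix-class] with K >= 2 samples in file order.
#' @export
readExpressionTSV <- function(path, mode = c("abundance", "log_fold_change")) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    .parseError(sprintf("expression file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 2L)
    .parseError("expression file needs a header line and at least one gene row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (header[1L] != "gene_id")
    .parseError("expression header must start with 'gene_id'")
  samples <- header[-1L]
  if (length(samples) < 2L)
    .validationError("at least 2 sample columns are required (fold changes need K >= 2)")
  if (anyDuplicated(samples))
    .validationError("duplicated sample names in header")

  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != length(header)))
    .parseError(sprintf("row %d has %d fields (%d expected)",
                        which(nc != length(header))[1L],
                        nc[nc != length(header)][1L], length(header)))
  genes <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    .validationError(sprintf("duplicated gene identifier '%s'",
                             genes[duplicated(genes)][1L]))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(rows, `[`, -1L), use.names = FALSE)),
           nrow = length(rows), ncol = length(samples), byrow = TRUE,
           dimnames = list(genes, samples)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    .parseError(sprintf("non-numeric value at gene row %d ('%s'), column '%s'",
                        bad[1L, 1L], genes[bad[1L, 1L]],
                        samples[bad[1L, 2L]]))
  .log("INFO", sprintf("read %d genes x %d samples from %s",
                       length(genes), length(samples), path))
  for (s in samples)
    .log("DEBUG", sprintf("  sample %s: median %.4g, max %.4g",
                          s, stats::median(vals[, s]), max(vals[, s])))
  ExpressionMatrix(vals, mode = mode)
}

#' Write an ExpressionMatrix as TSV
#'
#' Deterministic serialization (15 significant digits) in the dialect read
#' by [readExpressionTSV()].
#'
#' @param expr An [ExpressionMatrix-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTSV <- function(expr, path) {
  v <- exprValues(expr)
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], .fmtNum(v[i, ], digits = 15L)), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("gene_id", colnames(v)), collapse = "\t"), body), path)
  invisible(path)
}
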