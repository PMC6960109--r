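#' Construct an expression matrix
#'
#' A light container for a real-valued subjects-by-genes matrix together with
#' its identifiers and a scale tag. Rows are subjects (samples), columns are
#' genes (or probes before collapsing). Raw-scale entries must be
#' non-negative; the `log10p1` tag marks data already passed through
#' [log_transform()].
#'
#' @param values Numeric matrix, subjects in rows and genes in columns.
#'   Missing entries (positions flagged 0 in an accompanying observation
#'   mask) are conventionally stored as 0.
#' @param sample_ids Character vector of row identifiers; defaults to
#'   existing rownames or `S1..Sm`.
#' @param gene_ids Character vector of column identifiers; defaults to
#'   existing colnames or `G1..Gn`.
#' @param scale_tag Either `"raw"` (non-negative intensities) or `"log10p1"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `sample_ids`, `gene_ids`, `scale_tag`.
#' @examples
#' em <- expression_matrix(matrix(1:6, 2, 3))
#' dim(em)
#' @export
expression_matrix <- function(values,
                              sample_ids = NULL,
                              gene_ids = NULL,
                              scale_tag = c("raw", "log10p1")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values))
    stop("number of sample_ids (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("number of gene_ids (", length(gene_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite entries present; encode missing values through an observation mask")
  if (scale_tag == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values,
         sample_ids = as.character(sample_ids),
         gene_ids = as.character(gene_ids),
         scale_tag = scale_tag),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d subjects x %d genes [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' Read a delimited expression matrix and its observation mask
#'
#' Reads a delimited text file whose first row holds sample identifiers and
#' whose first column holds gene (or probe) identifiers, i.e. genes in rows,
#' the usual layout of exported expression tables. The matrix is transposed
#' into the internal subjects-by-genes orientation. Cells equal to
#' `missing_sentinel` or left empty are treated as missing: they become 0 in
#' the value matrix and 0 in the returned observation mask.
#'
#' @param path Path to the file.
#' @param missing_sentinel String marking a missing cell (default `"NA"`);
#'   empty cells are always treated as missing.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param genes_in_rows If `TRUE` (default) the file stores genes in rows
#'   and samples in columns; set `FALSE` for the transposed layout.
#' @param scale_tag Scale tag to stamp on the result (`"raw"` or `"log10p1"`).
#' @return A list with `matrix` (an [expression_matrix()]) and `mask`
#'   (binary subjects-by-genes matrix, 1 = observed).
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, missing_sentinel = "NA", sep = "\t",
                        genes_in_rows = TRUE, scale_tag = "raw") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = NULL, colClasses = "character",
                      na.strings = character(), comment.char = "",
                      quote = "\"", fill = FALSE, blank.lines.skip = FALSE),
    error = function(e) stop("parse error in '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (ncol(df) < 2) stop("'", path, "' has no data columns")
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]      # before subsetting: `[.data.frame`
  cells <- as.matrix(df[, -1, drop = FALSE])   # silently deduplicates names
  colnames(cells) <- col_ids
  miss <- cells == missing_sentinel | cells == ""
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  vals[miss] <- 0
  bad <- !miss & !is.finite(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[bad][1], "' at data row ", idx[1],
         ", column '", col_ids[idx[2]], "' of '", path, "'")
  }
  mask <- 1 - miss * 1L
  if (genes_in_rows) {
    vals <- t(vals); mask <- t(mask)
    sample_ids <- col_ids; gene_ids <- row_ids
  } else {
    sample_ids <- row_ids; gene_ids <- col_ids
  }
  dimnames(vals) <- dimnames(mask) <- list(sample_ids, gene_ids)
  em <- expression_matrix(vals, sample_ids, gene_ids, scale_tag = scale_tag)
  list(matrix = em, mask = mask)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_matrix()]: genes in rows, samples in columns, missing
#' positions (mask 0) written as the sentinel. Values are formatted with
#' `digits` significant digits.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @param mask Optional observation mask; positions with 0 are written as
#'   `missing_sentinel`.
#' @param missing_sentinel String to write for missing cells.
#' @param sep Field separator.
#' @param digits Significant digits for numeric output.
#' @param genes_in_rows Write genes in rows (default) or transposed.
#' @export
write_matrix <- function(em, path, mask = NULL, missing_sentinel = "NA",
                         sep = "\t", digits = 6, genes_in_rows = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  vals <- em$values
  cells <- array(trimws(formatC(vals, digits = digits, format = "g")),
                 dim = dim(vals))
  if (!is.null(mask)) cells[mask == 0] <- missing_sentinel
  if (genes_in_rows) {
    cells <- t(cells)
    out <- data.frame(gene_id = em$gene_ids, cells, check.names = FALSE)
    colnames(out) <- c("gene_id", em$sample_ids)
  } else {
    out <- data.frame(sample_id = em$sample_ids, cells, check.names = FALSE)
    colnames(out) <- c("sample_id", em$gene_ids)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column delimited file: probe_id, gene_symbol. Probe ids must be
#' unique and gene symbols non-empty.
#'
#' @param path Path to the mapping file.
#' @param sep Field separator.
#' @param header Whether the file has a header row.
#' @return A data.frame with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path, sep = "\t", header = TRUE) {
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("probe map must have two columns (probe_id, gene_symbol)")
  pm <- data.frame(probe_id = df[[1]], gene_symbol = df[[2]],
                   stringsAsFactors = FALSE)
  validate_probe_map(pm)
}

#' @rdname read_probe_map
#' @param map A data.frame with columns `probe_id`, `gene_symbol` to validate.
#' @export
validate_probe_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("probe_id", "gene_symbol") %in% names(map)))
  if (anyDuplicated(map$probe_id))
    stop("duplicate probe ids in map: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  if (any(!nzchar(map$gene_symbol)))
    stop("empty gene symbols in probe map")
  map
}

#' Collapse probe-level columns to gene symbols by averaging
#'
#' Multiple microarray probes frequently interrogate the same gene; their
#' expression values are averaged into a single gene column. Averaging is
#' missing-aware: only observed probe entries contribute, and an output
#' entry is missing when every mapped probe is missing at that sample.
#' Probes absent from the map are dropped (with a message).
#'
#' @param em An [expression_matrix()] whose columns are probe ids.
#' @param map Probe map as returned by [read_probe_map()].
#' @param mask Optional observation mask aligned with `em` (default: all
#'   observed).
#' @return A list with `matrix` (gene-level [expression_matrix()], columns
#'   ordered by first appearance of each gene among the kept probes) and
#'   `mask` (gene-level observation mask).
#' @export
collapse_probes <- function(em, map, mask = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  map <- validate_probe_map(map)
  if (is.null(mask)) mask <- matrix(1, nrow(em$values), ncol(em$values))
  keep <- em$gene_ids %in% map$probe_id
  if (!any(keep)) stop("no probes in the matrix are present in the probe map")
  if (any(!keep))
    message(sum(!keep), " probe(s) absent from the map were dropped")
  vals <- em$values[, keep, drop = FALSE]
  msk <- mask[, keep, drop = FALSE]
  probes <- em$gene_ids[keep]
  genes <- map$gene_symbol[match(probes, map$probe_id)]
  ugenes <- unique(genes)
  grp <- match(genes, ugenes)
  # observed-entry sums and counts per gene group
  num <- (vals * msk) %*% outer(grp, seq_along(ugenes), "==")
  cnt <- msk %*% outer(grp, seq_along(ugenes), "==")
  out <- ifelse(cnt > 0, num / pmax(cnt, 1), 0)
  out_mask <- (cnt > 0) * 1
  dimnames(out) <- dimnames(out_mask) <- list(em$sample_ids, ugenes)
  list(matrix = expression_matrix(out, em$sample_ids, ugenes,
                                  scale_tag = em$scale_tag),
       mask = out_mask)
}

#' Log-transform a raw-scale expression matrix
#'
#' Applies x -> log10(x + 1) entrywise to compress the dynamic range of raw
#' intensities (which can span six orders of magnitude) so that small values
#' are not shadowed by large ones during recovery. Guarded by the scale tag:
#' transforming twice is an error. An accompanying observation mask is
#' unaffected (log10(0 + 1) = 0, so missing placeholders stay 0).
#'
#' @param em An [expression_matrix()] with `scale_tag == "raw"`.
#' @return The transformed [expression_matrix()] with `scale_tag "log10p1"`.
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale_tag != "raw")
    stop("log_transform expects raw-scale data; got scale_tag '", em$scale_tag, "'")
  if (any(em$values < 0)) stop("negative entries cannot be log-transformed")
  expression_matrix(log10(em$values + 1), em$sample_ids, em$gene_ids,
                    scale_tag = "log10p1")
}
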