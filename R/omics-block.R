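#' Construct an expression block
#'
#' An `omics_block` holds one RNA type's expression matrix in features x
#' samples orientation, together with unique feature and sample identifiers.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @param name Label for the block, e.g. `"mRNA"`.
#' @return An object of class `omics_block`: a list with elements `name`,
#'   `feature_ids`, `sample_ids` and `values` (dimnames set from the ids).
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' b <- omics_block(m, name = "mRNA")
#' dim(b)
#' @export
omics_block <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values), name = "block") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) stop("feature_ids are required (or set rownames)")
  if (is.null(sample_ids)) stop("sample_ids are required (or set colnames)")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids))
    stop("row count (", nrow(values), ") != number of feature_ids (",
         length(feature_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("column count (", ncol(values), ") != number of sample_ids (",
         length(sample_ids), ")")
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at feature '", feature_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(name = as.character(name)[1], feature_ids = feature_ids,
                 sample_ids = sample_ids, values = values),
            class = "omics_block")
}

#' @export
dim.omics_block <- function(x) dim(x$values)

#' @export
print.omics_block <- function(x, ...) {
  cat("<omics_block> '", x$name, "': ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Parses a delimited text matrix with identifiers in the first row and
#' column into an [omics_block]. Duplicated identifiers and non-numeric or
#' non-finite cells are rejected with informative errors.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter; `"\t"` (default) or `","`.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned block is always features x samples.
#' @param name Block label.
#' @return An [omics_block].
#' @export
read_expression <- function(path, delimiter = "\t",
                            orientation = c("features_in_rows", "samples_in_rows"),
                            name = "block") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("no data columns parsed from ", path)
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(vals), arr.ind = TRUE)
    stop("non-numeric cell at data row ", bad[1, 1], " (id '",
         row_ids[bad[1, 1]], "'), column ", bad[1, 2], " (id '",
         col_ids[bad[1, 2]], "')")
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") vals <- t(vals)
  omics_block(vals, name = name)
}

#' Write an expression block as delimited text
#'
#' Inverse of [read_expression]: feature identifiers in the first column,
#' sample identifiers in the header row.
#'
#' @param block An [omics_block].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(block, path, delimiter = "\t") {
  stopifnot(inherits(block, "omics_block"))
  df <- data.frame(feature_id = block$feature_ids, block$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
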