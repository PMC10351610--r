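#' Align blocks on a shared sample set
#'
#' Restricts each block to the intersection of all blocks' sample IDs,
#' reorders every block to a single shared (lexicographic) sample order, and
#' records block boundaries along the concatenated feature axis.
#'
#' @param blocks A list of [omics_block] objects (at least one).
#' @return An object of class `multi_omics`: list with `blocks` (aligned),
#'   `sample_ids` (shared order) and `boundaries` (data frame with columns
#'   `block`, `start`, `end`; 1-based inclusive row ranges into the
#'   concatenated matrix).
#' @examples
#' b1 <- omics_block(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                     c("s1", "s2"))))
#' b2 <- omics_block(matrix(1:4, 2, 2, dimnames = list(paste0("m", 1:2),
#'                                                     c("s2", "s1"))))
#' ms <- align_samples(list(b1, b2))
#' ms$boundaries
#' @export
align_samples <- function(blocks) {
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  if (length(blocks) < 1) stop("at least one block is required")
  stopifnot(all(vapply(blocks, inherits, logical(1), "omics_block")))
  shared <- Reduce(intersect, lapply(blocks, `[[`, "sample_ids"))
  if (length(shared) == 0) stop("sample intersection across blocks is empty")
  shared <- sort(shared)
  blocks <- lapply(blocks, function(b)
    omics_block(b$values[, shared, drop = FALSE], name = b$name))
  sizes <- vapply(blocks, function(b) nrow(b$values), integer(1))
  end <- cumsum(sizes)
  boundaries <- data.frame(block = vapply(blocks, `[[`, character(1), "name"),
                           start = c(1L, utils::head(end, -1) + 1L),
                           end = end, stringsAsFactors = FALSE)
  structure(list(blocks = blocks, sample_ids = shared,
                 boundaries = boundaries),
            class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat("<multi_omics> ", length(x$blocks), " block(s), ",
      length(x$sample_ids), " shared samples\n", sep = "")
  for (b in x$blocks)
    cat("  ", b$name, ": ", nrow(b$values), " features\n", sep = "")
  invisible(x)
}

#' Concatenate aligned blocks along the feature axis
#'
#' Row-stacks the aligned blocks into one total_features x samples matrix;
#' slicing the result by the recorded boundaries reproduces each block.
#'
#' @param ms A [multi_omics] object from [align_samples].
#' @return Numeric matrix (total features x shared samples) with a
#'   `boundaries` attribute.
#' @export
concatenate_blocks <- function(ms) {
  stopifnot(inherits(ms, "multi_omics"))
  x <- do.call(rbind, lapply(ms$blocks, `[[`, "values"))
  attr(x, "boundaries") <- ms$boundaries
  x
}

#' Total feature count of a multi_omics set
#' @param ms A [multi_omics] object.
#' @return Integer.
#' @export
n_features <- function(ms) {
  stopifnot(inherits(ms, "multi_omics"))
  sum(vapply(ms$blocks, function(b) nrow(b$values), integer(1)))
}

#' All feature IDs along the concatenated axis
#' @param ms A [multi_omics] object.
#' @return Character vector in block order.
#' @export
feature_ids <- function(ms) {
  stopifnot(inherits(ms, "multi_omics"))
  unlist(lapply(ms$blocks, `[[`, "feature_ids"), use.names = FALSE)
}

#' Write feature sets in GMT-like format
#'
#' One line per set: set name, description, then tab-separated member IDs.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Single description string recycled across sets.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "comodica") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
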