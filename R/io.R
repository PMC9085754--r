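# tab-separated I/O helpers shared by all stages; everything is plain text
# with a header so outputs stay diff-friendly and language-neutral

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV into a data.frame
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a named matrix as TSV (row ids in the first column)
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param id_col name of the id column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a TSV written by [write_matrix_tsv()] back into a matrix
#' @param path file path.
#' @return matrix with dimnames (numeric if all cells are numeric, else
#'   character).
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a GMT gene-set file
#'
#' Standard tab format: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @param universe optional background universe (defaults to the union of
#'   all term genes).
#' @return an [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": need term, description, >=1 gene",
           call. = FALSE)
    terms[[f[1]]] <- f[-(1:2)]
    descriptions[f[1]] <- f[2]
  }
  annotation_set(terms, universe = universe, descriptions = descriptions)
}

#' Write an annotation set as GMT
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  lines <- vapply(names(annotations$terms), function(tm) {
    paste(c(tm, annotations$descriptions[[tm]], annotations$terms[[tm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an undirected network as a SIF file
#' @param net an igraph graph.
#' @param path output path.
#' @param interaction interaction-type label for the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, interaction = "interacts") {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], interaction, el[, 2], sep = "\t"), path)
  invisible(path)
}
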