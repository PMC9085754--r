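#' Classify LN_IC50 values as sensitive/resistant
#'
#' Applies the strict sign rule: values greater than 0 are resistant, values
#' less than 0 sensitive. Exactly 0 and missing values are `"unclassified"`
#' (the published rule uses strict inequalities; no side-assignment is
#' invented for the boundary).
#'
#' @param ln_ic50 numeric vector of log-normalized IC50 values.
#' @return character vector in `{"sensitive", "resistant", "unclassified"}`.
#' @export
classify_response <- function(ln_ic50) {
  out <- rep("unclassified", length(ln_ic50))
  out[!is.na(ln_ic50) & ln_ic50 > 0] <- "resistant"
  out[!is.na(ln_ic50) & ln_ic50 < 0] <- "sensitive"
  names(out) <- names(ln_ic50)
  out
}

#' Select extreme responders per drug
#'
#' Selects the extreme drug-sensitive (`LN_IC50 < sensitive_cut`) and
#' drug-resistant (`LN_IC50 > resistant_cut`) samples per drug, labels every
#' non-missing entry via [classify_response()], and flags drugs whose
#' selection contains only one class (or none): such drugs permit no
#' differential contrast and are excluded from differential expression.
#'
#' @param values numeric cell-line x drug matrix of LN_IC50 values (row and
#'   column names required).
#' @param sensitive_cut,resistant_cut selection cuts (defaults -1 / +1);
#'   `sensitive_cut < resistant_cut` is required.
#' @return a `response_classification`: list with
#'   \describe{
#'     \item{calls}{long data.frame `cell_line`, `drug`, `ln_ic50`, `label`,
#'       `selected`.}
#'     \item{drugs}{per-drug summary: selected sensitive/resistant counts,
#'       `status` in `{"two-class", "single-class", "empty"}` and
#'       `excluded_from_dge`.}
#'     \item{cuts}{the cuts used.}
#'   }
#' @export
select_extremes <- function(values, sensitive_cut = -1, resistant_cut = 1) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry cell-line row names and drug column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("cell-line and drug ids must be unique", call. = FALSE)
  if (!(sensitive_cut < resistant_cut))
    stop("sensitive_cut must be smaller than resistant_cut", call. = FALSE)
  calls <- data.frame(
    cell_line = rep(rownames(values), times = ncol(values)),
    drug = rep(colnames(values), each = nrow(values)),
    ln_ic50 = as.vector(values),
    stringsAsFactors = FALSE
  )
  calls$label <- classify_response(calls$ln_ic50)
  calls$selected <- !is.na(calls$ln_ic50) &
    (calls$ln_ic50 < sensitive_cut | calls$ln_ic50 > resistant_cut)

  per_drug <- lapply(split(calls, calls$drug), function(d) {
    n_sens <- sum(d$selected & d$label == "sensitive")
    n_res <- sum(d$selected & d$label == "resistant")
    status <- if (n_sens > 0 && n_res > 0) "two-class"
              else if (n_sens == 0 && n_res == 0) "empty"
              else "single-class"
    data.frame(drug = d$drug[1], n_selected_sensitive = n_sens,
               n_selected_resistant = n_res, status = status,
               excluded_from_dge = status != "two-class",
               stringsAsFactors = FALSE)
  })
  drugs <- do.call(rbind, per_drug[colnames(values)])
  rownames(drugs) <- NULL
  structure(list(calls = calls, drugs = drugs,
                 cuts = c(sensitive = sensitive_cut,
                          resistant = resistant_cut)),
            class = "response_classification")
}

#' Uncentered correlation (cosine similarity)
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, with no mean-centering. Pairs with
#' a missing value in either vector are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must have equal positive length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 1L)
    stop("no complete pairs between x and y", call. = FALSE)
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    stop("undefined similarity: zero-norm vector", call. = FALSE)
  sum(x * y) / sqrt(nx * ny)
}

# pairwise uncentered-correlation distance matrix over rows
uncentered_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- 1 - uncentered_correlation(mat[i, ], mat[j, ])
    }
  }
  d
}

#' Hierarchical clustering with uncentered correlation and average linkage
#'
#' Agglomerative UPGMA clustering on the dissimilarity
#' `d = 1 - uncentered_correlation`, the metric used for response heatmaps.
#' Leaf order is made deterministic: at each merge, the subtree containing the
#' smallest original index goes left.
#'
#' @param mat numeric matrix; rows or columns are clustered.
#' @param axis `"rows"` or `"cols"`.
#' @return list with `hclust` (the [stats::hclust] tree, its `order` replaced
#'   by the deterministic one), `order` (integer leaf order), `labels`, and
#'   `heights`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") mat <- t(mat)
  if (nrow(mat) < 2L)
    stop("need at least 2 items to cluster", call. = FALSE)
  d <- uncentered_dist(mat)
  h <- hclust(as.dist(d), method = "average")
  ord <- deterministic_leaf_order(h$merge)
  h$order <- ord
  list(hclust = h, order = ord, labels = rownames(mat), heights = h$height)
}

# leaf order from an hclust merge matrix with the smallest-original-index
# tie-break: the child subtree whose minimum leaf index is smaller goes left
deterministic_leaf_order <- function(merge) {
  m <- nrow(merge)
  mins <- integer(m)
  ords <- vector("list", m)
  fetch <- function(k) {
    if (k < 0) list(min = -k, ord = -k)
    else list(min = mins[k], ord = ords[[k]])
  }
  for (i in seq_len(m)) {
    a <- fetch(merge[i, 1])
    b <- fetch(merge[i, 2])
    ords[[i]] <- if (a$min <= b$min) c(a$ord, b$ord) else c(b$ord, a$ord)
    mins[i] <- min(a$min, b$min)
  }
  ords[[m]]
}

#' Write a reordered matrix as a plot-ready TSV
#'
#' Reorders rows and columns by the supplied permutations (e.g. clustering
#' leaf orders) and writes the result, optionally with a per-row class
#' annotation column, for external heatmap rendering.
#'
#' @param mat numeric matrix with dimnames.
#' @param row_order,col_order integer permutations of the row/column indices.
#' @param path output TSV path.
#' @param row_annotation optional named character vector (per original row).
#' @return the reordered matrix, invisibly.
#' @export
export_heatmap_table <- function(mat, row_order, col_order, path,
                                 row_annotation = NULL) {
  check_perm <- function(p, n, what) {
    if (length(p) != n || !setequal(p, seq_len(n)))
      stop(what, " is not a permutation of 1..", n, call. = FALSE)
  }
  check_perm(row_order, nrow(mat), "row_order")
  check_perm(col_order, ncol(mat), "col_order")
  out <- mat[row_order, col_order, drop = FALSE]
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(row_annotation))
    df$annotation <- unname(row_annotation[rownames(out)])
  write_tsv(df, path)
  invisible(out)
}
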