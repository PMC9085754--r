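# vectorized Welch machinery shared by welch_t_test() and run_dge()
welch_from_moments <- function(ma, mb, va, vb, na, nb) {
  sea <- va / na
  seb <- vb / nb
  se2 <- sea + seb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (sea^2 / (na - 1) + seb^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  equal <- degenerate & (ma == mb)
  # both variances zero, equal means: no evidence of difference by convention
  t_stat[equal] <- 0
  df[equal] <- na + nb - 2
  p[equal] <- 1
  # both variances zero, unequal means: Welch statistic undefined
  undef <- degenerate & !equal
  t_stat[undef] <- sign(ma[undef] - mb[undef]) * Inf
  df[undef] <- NA_real_
  p[undef] <- NA_real_
  list(t = t_stat, df = df, p = p, degenerate_unequal = undef)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with the Welch approximation:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom. If both groups have zero variance
#' and equal means, `p = 1` by convention; if both variances are zero and the
#' means differ, the statistic is undefined and an error is raised.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (anyNA(group_a) || anyNA(group_b))
    stop("missing values in input groups", call. = FALSE)
  r <- welch_from_moments(mean(group_a), mean(group_b),
                          var(group_a), var(group_b),
                          length(group_a), length(group_b))
  if (r$degenerate_unequal)
    stop("degenerate variance: both groups constant with different means",
         call. = FALSE)
  list(t = r$t, df = r$df, p = r$p)
}

#' Log2 fold change between resistant and sensitive groups
#'
#' Difference of log2 means, `mean(resistant) - mean(sensitive)`; inputs are
#' assumed to be on the log2 scale already (RMA-style data), so a difference
#' of means is a log fold change.
#'
#' @param group_res,group_sens numeric vectors (log2 expression values).
#' @return numeric log2 fold change (positive = higher in resistant).
#' @export
log2_fold_change <- function(group_res, group_sens) {
  if (length(group_res) == 0L || length(group_sens) == 0L)
    stop("empty group", call. = FALSE)
  mean(group_res) - mean(group_sens)
}

#' Per-gene differential expression with double filtration
#'
#' Runs a row-wise Welch t-test (resistant vs sensitive) on a gene x sample
#' log2 expression matrix and applies the double filtration: a gene passes iff
#' `p < p_cut` and `|log2fc| > fc_cut`. `log2fc > 0` means higher expression
#' in the resistant class. Raw p-values are used by default; a
#' Benjamini-Hochberg column can be added with `fdr = TRUE` (the pass flag
#' still uses raw p).
#'
#' @param values gene x sample numeric matrix with dimnames.
#' @param classes named character vector mapping sample id to `"sensitive"` or
#'   `"resistant"`; samples absent from `classes` are ignored.
#' @param p_cut,fc_cut double-filtration cuts (defaults 0.05 and 2).
#' @param fdr add a BH-adjusted column?
#' @return a `deg_table` data.frame: `gene`, `t`, `df`, `p`, optional `fdr`,
#'   `log2fc`, `direction` (`"up"`/`"down"`), `pass`. Genes constant in both
#'   groups with equal means get `t = 0, p = 1, log2fc = 0`; constant with
#'   unequal means get `p = NA` and never pass (Welch undefined).
#' @export
run_dge <- function(values, classes, p_cut = 0.05, fc_cut = 2, fdr = FALSE) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop("values must be a gene x sample matrix with dimnames", call. = FALSE)
  classes <- classes[names(classes) %in% colnames(values)]
  res_samples <- names(classes)[classes == "resistant"]
  sens_samples <- names(classes)[classes == "sensitive"]
  if (length(res_samples) < 2L || length(sens_samples) < 2L)
    stop("no differential contrast: need >= 2 samples in each of the ",
         "sensitive and resistant classes", call. = FALSE)
  a <- values[, res_samples, drop = FALSE]   # resistant
  b <- values[, sens_samples, drop = FALSE]  # sensitive
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  r <- welch_from_moments(ma, mb, va, vb, na, nb)
  log2fc <- ma - mb
  log2fc[va == 0 & vb == 0 & ma == mb] <- 0
  out <- data.frame(
    gene = rownames(values),
    t = unname(r$t),
    df = unname(r$df),
    p = unname(r$p),
    stringsAsFactors = FALSE
  )
  if (fdr) out$fdr <- p.adjust(out$p, method = "BH")
  out$log2fc <- unname(log2fc)
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out$pass <- !is.na(out$p) & out$p < p_cut & abs(out$log2fc) > fc_cut
  rownames(out) <- NULL
  structure(out,
            class = c("deg_table", "data.frame"),
            params = list(p_cut = p_cut, fc_cut = fc_cut,
                          n_resistant = na, n_sensitive = nb))
}

#' Genes differentially expressed across multiple drugs
#'
#' Counts, for each gene, the number of drugs whose DEG table marks it as
#' passing the double filtration, and retains genes recurrent in at least
#' `min_drugs` drugs.
#'
#' @param deg_tables named list of [run_dge()] tables (names = drug ids).
#' @param min_drugs minimum number of drugs (default 3).
#' @return data.frame `gene`, `n_drugs`, `drugs` (comma-separated), sorted by
#'   descending count then gene id. Attribute `pass_counts` carries the
#'   per-drug pass totals.
#' @export
cross_drug_intersection <- function(deg_tables, min_drugs = 3L) {
  if (length(deg_tables) < 1L)
    stop("need at least one DEG table", call. = FALSE)
  if (is.null(names(deg_tables)) || anyDuplicated(names(deg_tables)))
    stop("deg_tables must be uniquely named by drug", call. = FALSE)
  pass_lists <- lapply(deg_tables, function(d) d$gene[d$pass])
  counts <- table(unlist(pass_lists, use.names = FALSE))
  keep <- names(counts)[counts >= min_drugs]
  drugs_of <- vapply(keep, function(g) {
    paste(names(pass_lists)[vapply(pass_lists, function(s) g %in% s,
                                   logical(1))],
          collapse = ",")
  }, character(1))
  out <- data.frame(gene = keep,
                    n_drugs = as.integer(counts[keep]),
                    drugs = unname(drugs_of),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_drugs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pass_counts") <- vapply(pass_lists, length, integer(1))
  out
}
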