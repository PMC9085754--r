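#' Build a co-expression network by thresholded similarity
#'
#' Computes pairwise gene-gene similarity across samples (uncentered
#' correlation, i.e. cosine, or Pearson) and connects gene pairs whose
#' absolute similarity reaches `tau`. Stands in for service-derived
#' co-expression edges so the stage is self-contained; imported edge lists are
#' also accepted via [import_edge_list()].
#'
#' @param values gene x sample numeric matrix with dimnames.
#' @param gene_subset optional character vector restricting the genes used.
#' @param tau absolute-similarity edge threshold in (0, 1].
#' @param method `"uncentered"` (cosine, no centering) or `"pearson"`.
#' @param regulation optional named character vector (gene ->
#'   `"up"`/`"down"`/`"predicted"`) copied onto the nodes; defaults to
#'   `"predicted"`.
#' @return an undirected [igraph][igraph::igraph-package] graph; edge
#'   attribute `weight` is the signed similarity, vertex attribute
#'   `regulation` the regulation status, graph attribute `provenance`
#'   `"coexpression"`. Genes whose similarity is undefined (zero norm under
#'   uncentered, zero variance under Pearson) are dropped with a warning.
#' @export
build_coexpression_network <- function(values, gene_subset = NULL, tau = 0.8,
                                       method = c("uncentered", "pearson"),
                                       regulation = NULL) {
  method <- match.arg(method)
  if (ncol(values) < 3L)
    stop("need at least 3 samples to estimate co-expression", call. = FALSE)
  if (!(tau > 0 && tau <= 1))
    stop("tau must lie in (0, 1]", call. = FALSE)
  if (!is.null(gene_subset))
    values <- values[intersect(gene_subset, rownames(values)), ,
                     drop = FALSE]
  if (nrow(values) < 2L)
    stop("need at least 2 genes", call. = FALSE)
  if (method == "pearson") {
    bad <- apply(values, 1, stats::sd) == 0
    if (any(bad)) {
      warning(sum(bad), " constant gene row(s) excluded under pearson")
      values <- values[!bad, , drop = FALSE]
    }
    sim <- stats::cor(t(values))
  } else {
    norms <- sqrt(rowSums(values^2))
    bad <- norms == 0
    if (any(bad)) {
      warning(sum(bad), " zero-norm gene row(s) excluded")
      values <- values[!bad, , drop = FALSE]
      norms <- norms[!bad]
    }
    sim <- (values %*% t(values)) / outer(norms, norms)
  }
  genes <- rownames(values)
  idx <- which(abs(sim) >= tau & upper.tri(sim), arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      weight = sim[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  reg <- rep("predicted", length(genes))
  names(reg) <- genes
  if (!is.null(regulation)) {
    hit <- intersect(names(regulation), genes)
    reg[hit] <- regulation[hit]
  }
  igraph::V(g)$regulation <- unname(reg[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "provenance", "coexpression")
  g
}

#' Import an undirected interaction edge list (SIF or TSV)
#'
#' Reads `node<TAB>interaction<TAB>node` SIF files or 2/3-column TSV edge
#' lists (`source`, `target`, optional numeric `confidence`). Edges are kept
#' when their confidence strictly exceeds `min_confidence` (the published
#' medium-confidence rule, "> 0.400"); unscored edges are kept only when
#' `min_confidence` is `NULL`. Duplicate undirected edges collapse to one,
#' keeping the maximum confidence.
#'
#' @param path file path; format chosen by extension (`.sif`) unless forced.
#' @param min_confidence strict lower confidence bound, or `NULL` to disable
#'   filtering (required for unscored inputs such as SIF).
#' @param format `"auto"`, `"sif"` or `"tsv"`.
#' @return an undirected igraph graph with edge attribute `confidence` and
#'   graph attribute `provenance = "imported"`.
#' @export
import_edge_list <- function(path, min_confidence = 0.400,
                             format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0); to <- character(0); conf <- numeric(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (format == "sif") {
      if (length(f) != 3L)
        stop("malformed SIF line ", i, ": expected 3 tab-separated fields",
             call. = FALSE)
      from <- c(from, f[1]); to <- c(to, f[3]); conf <- c(conf, NA_real_)
    } else {
      if (i == 1L && tolower(f[1]) %in% c("source", "from", "node1"))
        next  # header row
      if (length(f) == 2L) {
        from <- c(from, f[1]); to <- c(to, f[2]); conf <- c(conf, NA_real_)
      } else if (length(f) == 3L) {
        v <- suppressWarnings(as.numeric(f[3]))
        if (is.na(v))
          stop("malformed line ", i, ": non-numeric confidence '", f[3], "'",
               call. = FALSE)
        from <- c(from, f[1]); to <- c(to, f[2]); conf <- c(conf, v)
      } else {
        stop("malformed line ", i, ": expected 2 or 3 tab-separated fields",
             call. = FALSE)
      }
    }
  }
  if (!is.null(min_confidence)) {
    keep <- !is.na(conf) & conf > min_confidence
    from <- from[keep]; to <- to[keep]; conf <- conf[keep]
  }
  # collapse duplicate undirected edges, keeping the max confidence
  if (length(from)) {
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    best <- tapply(seq_along(key), key, function(ii) {
      if (all(is.na(conf[ii]))) ii[1] else ii[which.max(conf[ii])]
    })
    pick <- sort(unname(best))
    from <- from[pick]; to <- to[pick]; conf <- conf[pick]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, confidence = conf,
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::set_graph_attr(g, "provenance", "imported")
}

#' Node degrees of an undirected network
#'
#' @param net an igraph graph.
#' @return named integer vector, node -> number of incident edges.
#' @export
node_degrees <- function(net) {
  d <- igraph::degree(net, mode = "all", loops = FALSE)
  setNames(as.integer(d), igraph::V(net)$name)
}

#' Select hub nodes by degree
#'
#' Hubs are selected either by an absolute degree threshold
#' (`min_degree = k`: all nodes with degree >= k) or as the top fraction of
#' nodes by degree (`top_fraction = f`: the `ceiling(f * n)` highest-degree
#' nodes, with all ties at the cutoff included). Exactly one rule must be
#' given. The lowest selected degree is recorded, matching how published hub
#' tables report their cutoffs.
#'
#' @param net an igraph graph.
#' @param min_degree absolute degree threshold, or `NULL`.
#' @param top_fraction fraction in (0, 1], or `NULL`.
#' @param drug optional drug id recorded in the result.
#' @return a `hub_set`: list with `hubs` (character, ordered by decreasing
#'   degree then name), `rule`, `lowest_degree`, `degrees`, `drug`,
#'   `provenance`.
#' @export
select_hubs <- function(net, min_degree = NULL, top_fraction = NULL,
                        drug = NA_character_) {
  if (is.null(min_degree) == is.null(top_fraction))
    stop("give exactly one of min_degree or top_fraction", call. = FALSE)
  deg <- node_degrees(net)
  if (!is.null(top_fraction)) {
    if (!(top_fraction > 0 && top_fraction <= 1))
      stop("top_fraction must lie in (0, 1]", call. = FALSE)
    k <- ceiling(top_fraction * length(deg))
    cutoff <- sort(deg, decreasing = TRUE)[k]
    hubs <- names(deg)[deg >= cutoff]
    rule <- list(type = "top_fraction", value = top_fraction)
  } else {
    hubs <- names(deg)[deg >= min_degree]
    rule <- list(type = "min_degree", value = min_degree)
  }
  hubs <- hubs[order(-deg[hubs], hubs)]
  structure(list(hubs = hubs,
                 rule = rule,
                 lowest_degree = if (length(hubs)) min(deg[hubs]) else NA,
                 degrees = deg,
                 drug = drug,
                 provenance = if (!is.null(igraph::graph_attr(net,
                                                              "provenance")))
                   igraph::graph_attr(net, "provenance") else NA_character_),
            class = "hub_set")
}

#' Detect communities by greedy modularity maximization
#'
#' Partitions an undirected network into densely interconnected modules by
#' greedy modularity optimization (the same objective family as the GLay
#' community clustering used on published co-expression networks).
#' Deterministic for a given graph.
#'
#' @param net an undirected igraph graph.
#' @return a `community_partition`: list with `membership` (named integer),
#'   `modularity`, `n_communities`.
#' @export
detect_communities <- function(net) {
  if (igraph::vcount(net) < 1L)
    stop("need at least one node", call. = FALSE)
  if (igraph::ecount(net) == 0L) {
    membership <- setNames(seq_len(igraph::vcount(net)), igraph::V(net)$name)
    return(structure(list(membership = membership, modularity = 0,
                          n_communities = length(membership)),
                     class = "community_partition"))
  }
  cl <- igraph::cluster_fast_greedy(igraph::simplify(net), weights = NULL)
  # cut the dendrogram at the modularity maximum explicitly (the first
  # maximum, so ties resolve deterministically toward fewer merges)
  best <- which.max(cl$modularity)
  k <- igraph::vcount(net) - best + 1L
  membership <- setNames(as.integer(igraph::cut_at(cl, no = k)),
                         igraph::V(net)$name)
  structure(list(membership = membership,
                 modularity = max(cl$modularity),
                 n_communities = length(unique(membership))),
            class = "community_partition")
}

#' Intersect co-expression hubs with per-cluster PPI hubs
#'
#' For each PPI cluster, the genes that are hubs in both the co-expression
#' network and that cluster's protein-protein interaction network. Clusters
#' with an empty intersection are reported as `NA` (as in published
#' common-hub tables).
#'
#' @param coexp_hubs a [select_hubs()] `hub_set` or character vector.
#' @param ppi_hubs_by_cluster named list (cluster id -> `hub_set` or
#'   character vector).
#' @return named list, cluster -> sorted character vector of common hubs, or
#'   `NA_character_` when empty.
#' @export
intersect_hubs <- function(coexp_hubs, ppi_hubs_by_cluster) {
  as_genes <- function(x) if (inherits(x, "hub_set")) x$hubs else x
  cx <- as_genes(coexp_hubs)
  lapply(ppi_hubs_by_cluster, function(h) {
    common <- sort(intersect(cx, as_genes(h)))
    if (length(common) == 0L) NA_character_ else common
  })
}

#' Count drugs sharing each common-hub gene
#'
#' Given per-drug common-hub gene sets (each the union of that drug's
#' per-cluster common hubs), counts for each gene the number of distinct
#' drugs carrying it.
#'
#' @param per_drug_common_hubs named list, drug -> character vector of genes
#'   (or a list of per-cluster vectors, which is unioned; `NA` entries are
#'   dropped).
#' @return data.frame `gene`, `n_drugs`, `drugs` (comma-separated), sorted by
#'   descending count then gene id.
#' @export
common_across_drugs <- function(per_drug_common_hubs) {
  if (length(per_drug_common_hubs) < 2L)
    stop("need at least two drugs", call. = FALSE)
  sets <- lapply(per_drug_common_hubs, function(x) {
    g <- unique(unlist(x, use.names = FALSE))
    g[!is.na(g)]
  })
  counts <- table(unlist(sets, use.names = FALSE))
  genes <- names(counts)
  drugs_of <- vapply(genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = ",")
  }, character(1))
  out <- data.frame(gene = genes, n_drugs = as.integer(counts),
                    drugs = unname(drugs_of), stringsAsFactors = FALSE)
  out <- out[order(-out$n_drugs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
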