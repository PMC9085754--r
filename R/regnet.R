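#' Construct a directed regulatory network
#'
#' Builds a directed graph from a typed edge table, enforcing the container
#' invariants: every node carries exactly one class (`lncRNA`, `TF` or
#' `coding`; conflicting assignments are an error), self-loops are rejected,
#' and parallel edges are collapsed with their provenance tags merged.
#'
#' @param edges data.frame with columns `source`, `target`, `source_class`,
#'   `target_class`, and optionally `provenance`.
#' @param nodes optional data.frame `node`, `class` adding isolated nodes.
#' @return a directed igraph graph with vertex attribute `class` and edge
#'   attribute `provenance` (comma-joined tags).
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  req <- c("source", "target", "source_class", "target_class")
  if (!all(req %in% names(edges)))
    stop("edges must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(edges$source == edges$target))
    stop("self-loops are not allowed in a regulatory network", call. = FALSE)
  if (is.null(edges$provenance)) edges$provenance <- "curated"
  cls <- data.frame(node = c(edges$source, edges$target),
                    class = c(edges$source_class, edges$target_class),
                    stringsAsFactors = FALSE)
  if (!is.null(nodes)) cls <- rbind(cls, nodes[, c("node", "class")])
  cls <- unique(cls)
  dup <- cls$node[duplicated(cls$node)]
  if (length(dup))
    stop("conflicting node class for: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(cls$class, c("lncRNA", "TF", "coding"))
  if (length(bad))
    stop("unknown node class: ", paste(bad, collapse = ", "), call. = FALSE)
  # collapse parallel edges, keeping all provenance tags
  key <- paste(edges$source, edges$target, sep = "\r")
  prov <- tapply(edges$provenance, key, function(p)
    paste(sort(unique(unlist(strsplit(p, ",", fixed = TRUE)))),
          collapse = ","))
  first <- !duplicated(key)
  e <- edges[first, c("source", "target"), drop = FALSE]
  e$provenance <- unname(prov[key[first]])
  g <- igraph::graph_from_data_frame(
    e, directed = TRUE,
    vertices = data.frame(name = cls$node, class = cls$class,
                          stringsAsFactors = FALSE))
  g
}

#' Merge directed regulatory edge sets into one master network
#'
#' Unions several typed edge tables (e.g. TF-gene interactions from a
#' curated repository plus text-mined lncRNA-TF and lncRNA-gene relations)
#' into a single [regulatory_network()], collapsing edges present in several
#' sets while keeping all their provenance tags. A node assigned different
#' classes in different sets is an error.
#'
#' @param edge_sets list of edge data.frames (see [regulatory_network()]).
#' @return a directed igraph graph.
#' @export
merge_networks <- function(edge_sets) {
  if (length(edge_sets) < 1L) stop("no edge sets supplied", call. = FALSE)
  merged <- do.call(rbind, lapply(edge_sets, function(e) {
    if (is.null(e$provenance)) e$provenance <- "curated"
    e[, c("source", "target", "source_class", "target_class", "provenance")]
  }))
  regulatory_network(merged)
}

#' Node and edge counts of a regulatory network by class
#'
#' @param net a directed igraph regulatory network.
#' @return list with `n_nodes`, `n_edges`, and `n_by_class`.
#' @export
network_summary <- function(net) {
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       n_by_class = table(igraph::V(net)$class))
}

#' Out-degree of every node
#'
#' @param net a directed igraph graph.
#' @return named integer vector, node -> number of outgoing edges.
#' @export
out_degree <- function(net) {
  d <- igraph::degree(net, mode = "out", loops = FALSE)
  setNames(as.integer(d), igraph::V(net)$name)
}

#' Directed betweenness centrality, normalized to [0, 1]
#'
#' Fraction of shortest directed paths between ordered node pairs passing
#' through each node, computed by Brandes' algorithm on unweighted (hop-count)
#' paths and normalized by `(n - 1) * (n - 2)`. Unreachable pairs contribute
#' nothing.
#'
#' @param net a directed igraph graph.
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  vs <- igraph::V(net)$name
  n <- length(vs)
  bc <- setNames(numeric(n), vs)
  if (n < 3L) return(bc)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net), mode = "out"),
                as.integer)
  for (s in seq_len(n)) {
    # BFS from s counting shortest paths (sigma) and predecessors
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / ((n - 1) * (n - 2))
}

#' Per-node centrality table
#'
#' @param net a directed igraph regulatory network.
#' @return data.frame `node`, `class`, `out_degree`, `betweenness`.
#' @export
centrality_table <- function(net) {
  data.frame(node = igraph::V(net)$name,
             class = igraph::V(net)$class,
             out_degree = unname(out_degree(net)),
             betweenness = unname(betweenness_centrality(net)),
             stringsAsFactors = FALSE)
}

#' Rank candidate master regulators within a node class
#'
#' Orders the nodes of one class by out-degree (primary), betweenness
#' centrality (secondary), and node id (tie-break); the top node is the
#' nominated master regulator for that class.
#'
#' @param net a directed igraph regulatory network, or a [centrality_table()]
#'   data.frame.
#' @param node_class class to rank (`"lncRNA"`, `"TF"` or `"coding"`).
#' @return the filtered centrality table with a `rank` column, best first.
#' @export
rank_regulators <- function(net, node_class) {
  ct <- if (is.data.frame(net)) net else centrality_table(net)
  ct <- ct[ct$class == node_class, , drop = FALSE]
  if (nrow(ct) == 0L)
    stop("no nodes of class '", node_class, "'", call. = FALSE)
  ct <- ct[order(-ct$out_degree, -ct$betweenness, ct$node), , drop = FALSE]
  ct$rank <- seq_len(nrow(ct))
  rownames(ct) <- NULL
  ct
}

#' Two-hop indirect coding targets of a regulator
#'
#' All pairs (coding gene g, transcription factor t) such that the network
#' contains `source -> t` and `t -> g`: the source regulates g indirectly via
#' the mediating TF t.
#'
#' @param net a directed igraph regulatory network.
#' @param source node id of the regulator.
#' @return data.frame `target`, `via` (one row per (target, mediator) pair,
#'   deduplicated, sorted).
#' @export
two_hop_indirect_targets <- function(net, source) {
  if (!source %in% igraph::V(net)$name)
    stop("source node '", source, "' not in network", call. = FALSE)
  cls <- setNames(igraph::V(net)$class, igraph::V(net)$name)
  step1 <- names(igraph::neighbors(net, source, mode = "out"))
  tfs <- step1[cls[step1] == "TF"]
  out <- data.frame(target = character(0), via = character(0),
                    stringsAsFactors = FALSE)
  for (t in tfs) {
    g2 <- names(igraph::neighbors(net, t, mode = "out"))
    g2 <- g2[cls[g2] == "coding"]
    if (length(g2))
      out <- rbind(out, data.frame(target = g2, via = t,
                                   stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$target, out$via), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutual (bidirectional) regulatory edges
#'
#' All unordered node pairs connected by directed edges in both directions -
#' the feedback-loop signature (e.g. a TF regulating a lncRNA that also
#' regulates the TF).
#'
#' @param net a directed igraph graph.
#' @return data.frame `node1`, `node2` (lexicographically ordered within and
#'   across rows); zero rows when the graph has no reciprocal edges.
#' @export
find_mutual_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  out <- data.frame(node1 = character(0), node2 = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(el)) {
    fwd <- paste(el[, 1], el[, 2], sep = "\r")
    rev <- paste(el[, 2], el[, 1], sep = "\r")
    mut <- el[fwd %in% rev & el[, 1] < el[, 2], , drop = FALSE]
    if (nrow(mut))
      out <- data.frame(node1 = mut[, 1], node2 = mut[, 2],
                        stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a regulator-target pair as cis or trans
#'
#' `cis` iff the two genes lie on the same chromosome, `trans` otherwise.
#'
#' @param regulator,target gene ids.
#' @param annot transcript annotation data.frame (columns `gene`, `chrom`).
#' @return `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(regulator, target, annot) {
  chrom_of <- function(g) {
    i <- match(g, annot$gene)
    if (is.na(i)) stop("gene '", g, "' is not annotated", call. = FALSE)
    annot$chrom[i]
  }
  if (chrom_of(regulator) == chrom_of(target)) "cis" else "trans"
}

#' Locate an interaction site within a transcript's regions
#'
#' Maps a site interval (1-based inclusive mRNA coordinates) onto the target
#' transcript's 5'UTR / CDS / 3'UTR structure. The region containing the site
#' midpoint (`floor((start + end) / 2)`) is reported, together with the
#' fraction of the site overlapping each region, so boundary-spanning sites
#' are fully described.
#'
#' @param site_start,site_end site interval on the target mRNA.
#' @param gene target gene id.
#' @param annot transcript annotation data.frame (see
#'   [simulate_transcript_annotation()] for the column layout).
#' @return list with `region` (`"5'UTR"`, `"CDS"` or `"3'UTR"`) and
#'   `overlap_fractions` (named numeric, sums to 1).
#' @export
annotate_interaction_region <- function(site_start, site_end, gene, annot) {
  i <- match(gene, annot$gene)
  if (is.na(i)) stop("gene '", gene, "' is not annotated", call. = FALSE)
  a <- annot[i, ]
  if (site_start > site_end)
    stop("site start must not exceed site end", call. = FALSE)
  if (site_start < 1L || site_end > a$utr3_end)
    stop("site [", site_start, ", ", site_end, "] lies outside the ",
         gene, " transcript (1-", a$utr3_end, ")", call. = FALSE)
  regions <- list(`5'UTR` = c(a$utr5_start, a$utr5_end),
                  CDS = c(a$cds_start, a$cds_end),
                  `3'UTR` = c(a$utr3_start, a$utr3_end))
  mid <- floor((site_start + site_end) / 2)
  region <- names(regions)[vapply(regions, function(r)
    mid >= r[1] && mid <= r[2], logical(1))]
  len <- site_end - site_start + 1
  frac <- vapply(regions, function(r) {
    ov <- min(site_end, r[2]) - max(site_start, r[1]) + 1
    max(ov, 0) / len
  }, numeric(1))
  list(region = region, overlap_fractions = frac)
}

#' Assemble the regulatory-axis report
#'
#' Nominates the master-regulator lncRNA (highest out-degree, then
#' betweenness), collects its direct targets by class, its two-hop indirect
#' coding targets with mediating TFs, its mutual-edge (feedback) partners,
#' and - when transcript annotation and interaction sites are supplied - a
#' cis/trans call and an interaction-region annotation per coding target.
#'
#' @param net a directed igraph regulatory network.
#' @param annot optional transcript annotation data.frame.
#' @param sites optional interaction-site data.frame with columns `lncRNA`,
#'   `target`, `start`, `end`.
#' @param regulator optional node id overriding the nomination.
#' @return an `axis_report` list; if the network has no lncRNA source with
#'   out-edges, a report with `no_regulator = TRUE`.
#' @export
build_axis_report <- function(net, annot = NULL, sites = NULL,
                              regulator = NULL) {
  cls <- setNames(igraph::V(net)$class, igraph::V(net)$name)
  if (is.null(regulator)) {
    if (!any(cls == "lncRNA") || igraph::ecount(net) == 0L)
      return(structure(list(regulator = NA_character_, no_regulator = TRUE),
                       class = "axis_report"))
    ranking <- rank_regulators(net, "lncRNA")
    if (ranking$out_degree[1] == 0L)
      return(structure(list(regulator = NA_character_, no_regulator = TRUE),
                       class = "axis_report"))
    regulator <- ranking$node[1]
  }
  direct <- names(igraph::neighbors(net, regulator, mode = "out"))
  direct_by_class <- split(direct, cls[direct])
  indirect <- two_hop_indirect_targets(net, regulator)
  mut <- find_mutual_edges(net)
  partners <- sort(unique(c(mut$node2[mut$node1 == regulator],
                            mut$node1[mut$node2 == regulator])))
  coding_targets <- sort(unique(c(direct[cls[direct] == "coding"],
                                  indirect$target)))
  cis_trans <- NULL
  if (!is.null(annot) && length(coding_targets)) {
    cis_trans <- vapply(coding_targets, function(g) {
      if (g %in% annot$gene && regulator %in% annot$gene)
        classify_cis_trans(regulator, g, annot)
      else NA_character_
    }, character(1))
  }
  regions <- NULL
  if (!is.null(sites) && !is.null(annot)) {
    s <- sites[sites$lncRNA == regulator, , drop = FALSE]
    if (nrow(s)) {
      regions <- data.frame(target = s$target, start = s$start, end = s$end,
                            region = vapply(seq_len(nrow(s)), function(i)
                              annotate_interaction_region(s$start[i],
                                                          s$end[i],
                                                          s$target[i],
                                                          annot)$region,
                              character(1)),
                            stringsAsFactors = FALSE)
    }
  }
  structure(list(regulator = regulator,
                 no_regulator = FALSE,
                 direct_targets = direct_by_class,
                 indirect_targets = indirect,
                 mutual_partners = partners,
                 coding_targets = coding_targets,
                 cis_trans = cis_trans,
                 interaction_regions = regions),
            class = "axis_report")
}

#' @export
print.axis_report <- function(x, ...) {
  if (isTRUE(x$no_regulator)) {
    cat("Regulatory-axis report: no regulator could be nominated\n")
    return(invisible(x))
  }
  cat("Regulatory-axis report\n")
  cat("  master regulator:", x$regulator, "\n")
  for (cl in names(x$direct_targets))
    cat("  direct", cl, "targets:",
        paste(sort(x$direct_targets[[cl]]), collapse = ", "), "\n")
  if (nrow(x$indirect_targets))
    cat("  indirect coding targets:",
        paste(sprintf("%s (via %s)", x$indirect_targets$target,
                      x$indirect_targets$via), collapse = ", "), "\n")
  if (length(x$mutual_partners))
    cat("  mutual-interaction partners:",
        paste(x$mutual_partners, collapse = ", "), "\n")
  if (!is.null(x$cis_trans))
    cat("  cis targets:",
        paste(names(x$cis_trans)[x$cis_trans == "cis"], collapse = ", "),
        "\n")
  invisible(x)
}
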