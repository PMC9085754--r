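#' Pipeline run configuration
#'
#' Collects input paths and every stage threshold for [run_all()]. Only
#' `response`, `expression` and `out_dir` are required; the regulatory,
#' PPI, enrichment and annotation stages run when their inputs are given.
#'
#' @param response path to the cell-line x drug LN_IC50 TSV
#'   ([write_matrix_tsv()] layout).
#' @param expression path to the gene x sample log2 expression TSV.
#' @param reg_edges optional path to a directed regulatory edge TSV
#'   (`source`, `target`, `source_class`, `target_class`, `provenance`).
#' @param ppi_edges optional path to an undirected PPI edge list (TSV/SIF).
#' @param gmt optional path to a GMT annotation file.
#' @param transcripts optional path to a transcript-annotation TSV.
#' @param sites optional path to an interaction-site TSV.
#' @param out_dir output directory.
#' @param sensitive_cut,resistant_cut extreme-responder cuts.
#' @param p_cut,fc_cut double-filtration cuts.
#' @param min_drugs cross-drug intersection threshold.
#' @param tau co-expression similarity threshold.
#' @param hub_top_fraction top-degree fraction for hub selection.
#' @param ppi_min_confidence strict confidence cut for PPI import (`NULL`
#'   keeps unscored edges).
#' @param fdr_cut enrichment significance threshold.
#' @param seed integer seed echoed into the run report.
#' @return a `run_config` list.
#' @export
run_config <- function(response, expression, reg_edges = NULL,
                       ppi_edges = NULL, gmt = NULL, transcripts = NULL,
                       sites = NULL, out_dir = tempfile("regaxis_run_"),
                       sensitive_cut = -1, resistant_cut = 1,
                       p_cut = 0.05, fc_cut = 2, min_drugs = 3L,
                       tau = 0.8, hub_top_fraction = 0.2,
                       ppi_min_confidence = 0.400, fdr_cut = 0.05,
                       seed = 1L) {
  structure(list(response = response, expression = expression,
                 reg_edges = reg_edges, ppi_edges = ppi_edges, gmt = gmt,
                 transcripts = transcripts, sites = sites, out_dir = out_dir,
                 sensitive_cut = sensitive_cut, resistant_cut = resistant_cut,
                 p_cut = p_cut, fc_cut = fc_cut,
                 min_drugs = as.integer(min_drugs), tau = tau,
                 hub_top_fraction = hub_top_fraction,
                 ppi_min_confidence = ppi_min_confidence,
                 fdr_cut = fdr_cut, seed = as.integer(seed)),
            class = "run_config")
}

#' Pre-flight validation of pipeline inputs
#'
#' Checks that the referenced files exist and parse, that ids are consistent
#' across files (classified samples appear in the expression matrix,
#' interaction-site genes are annotated, sites lie within their transcripts)
#' and that ids are unique. Findings are returned, severity-tagged, rather
#' than raised.
#'
#' @param config a [run_config()].
#' @return data.frame `severity` (`"error"`/`"warning"`), `message`; zero
#'   rows when the bundle is consistent.
#' @export
validate_inputs <- function(config) {
  findings <- data.frame(severity = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  note <- function(severity, message) {
    findings <<- rbind(findings,
                       data.frame(severity = severity, message = message,
                                  stringsAsFactors = FALSE))
  }
  required <- c("response", "expression")
  for (f in required) {
    if (is.null(config[[f]]))
      note("error", paste0("missing required input: ", f))
    else if (!file.exists(config[[f]]))
      note("error", paste0(f, " file not found: ", config[[f]]))
  }
  optional <- c("reg_edges", "ppi_edges", "gmt", "transcripts", "sites")
  for (f in optional) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      note("error", paste0(f, " file not found: ", config[[f]]))
  }
  if (nrow(findings)) return(findings)

  resp <- tryCatch(read_matrix_tsv(config$response), error = function(e) {
    note("error", paste0("response unreadable: ", conditionMessage(e)))
    NULL
  })
  expr <- tryCatch(read_matrix_tsv(config$expression), error = function(e) {
    note("error", paste0("expression unreadable: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(resp)) {
    if (anyDuplicated(rownames(resp)))
      note("warning", "duplicated cell-line ids in response matrix")
    if (!is.null(expr)) {
      shared <- intersect(rownames(resp), colnames(expr))
      if (length(shared) == 0L)
        note("error",
             "no cell line in the response matrix matches an expression column")
    }
  }
  if (!is.null(expr) && anyDuplicated(rownames(expr)))
    note("warning", "duplicated gene rows in expression matrix")
  if (!is.null(config$sites) && !is.null(config$transcripts)) {
    sites <- read_tsv(config$sites)
    annot <- read_tsv(config$transcripts)
    for (i in seq_len(nrow(sites))) {
      g <- sites$target[i]
      j <- match(g, annot$gene)
      if (is.na(j)) {
        note("error", paste0("site target '", g, "' missing from transcripts"))
      } else if (sites$end[i] > annot$utr3_end[j] || sites$start[i] < 1L) {
        note("error", paste0("site [", sites$start[i], ", ", sites$end[i],
                             "] outside the ", g, " transcript (1-",
                             annot$utr3_end[j], ")"))
      }
    }
  }
  findings
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order: extreme-responder classification
#' (drugs whose selection has a single class are excluded, with a logged
#' reason), per-drug Welch differential expression with double filtration,
#' cross-drug DEG intersection, per-drug co-expression networks with
#' degree-based hubs and modularity communities, per-community PPI hub
#' intersection, cross-drug common-hub counting, directed regulatory-network
#' analysis with the master-regulator axis report, and gene-set enrichment.
#' All intermediate tables are written as TSV under `config$out_dir`, plus a
#' machine-readable `run_report.json`.
#'
#' @param config a [run_config()]. Validation findings of severity `"error"`
#'   abort before any stage runs.
#' @return a `run_report` list: per-stage row counts, parameter echo,
#'   excluded drugs with reasons, and the embedded axis report.
#' @export
run_all <- function(config) {
  findings <- validate_inputs(config)
  if (any(findings$severity == "error"))
    stop("input validation failed:\n  ",
         paste(findings$message[findings$severity == "error"],
               collapse = "\n  "), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = unclass(config), stages = list(),
                 warnings = findings$message)

  # stage 1: response classification and extreme selection
  resp <- read_matrix_tsv(config$response)
  cls <- select_extremes(resp, config$sensitive_cut, config$resistant_cut)
  write_tsv(cls$calls, file.path(config$out_dir, "classification.tsv"))
  write_tsv(cls$drugs, file.path(config$out_dir, "drug_summary.tsv"))
  excluded <- cls$drugs[cls$drugs$excluded_from_dge, , drop = FALSE]
  report$stages$classification <- list(
    n_cell_lines = nrow(resp), n_drugs = ncol(resp),
    n_drugs_excluded = nrow(excluded),
    excluded_drugs = excluded$drug,
    exclusion_reasons = paste0(excluded$drug, ": ", excluded$status,
                               " selection"))

  # stage 2: per-drug differential expression
  expr <- read_matrix_tsv(config$expression)
  analyzable <- cls$drugs$drug[!cls$drugs$excluded_from_dge]
  deg_tables <- list()
  for (drug in analyzable) {
    d <- cls$calls[cls$calls$drug == drug & cls$calls$selected, , drop = FALSE]
    d <- d[d$cell_line %in% colnames(expr), , drop = FALSE]
    classes <- setNames(d$label, d$cell_line)
    if (sum(classes == "sensitive") < 2L || sum(classes == "resistant") < 2L) {
      report$stages$classification$exclusion_reasons <- c(
        report$stages$classification$exclusion_reasons,
        paste0(drug, ": fewer than 2 expression samples per class"))
      next
    }
    deg <- run_dge(expr, classes, p_cut = config$p_cut, fc_cut = config$fc_cut)
    write_tsv(deg, file.path(config$out_dir, paste0("deg_", drug, ".tsv")))
    deg_tables[[drug]] <- deg
  }
  report$stages$dge <- list(
    n_drugs_analyzed = length(deg_tables),
    pass_counts = lapply(deg_tables, function(d) sum(d$pass)))

  # stage 3: cross-drug intersection
  recurrent <- NULL
  if (length(deg_tables) >= 1L) {
    recurrent <- cross_drug_intersection(deg_tables,
                                         min_drugs = config$min_drugs)
    write_tsv(recurrent, file.path(config$out_dir, "recurrent_degs.tsv"))
    report$stages$intersection <- list(n_recurrent = nrow(recurrent),
                                       min_drugs = config$min_drugs)
  }

  # stage 4: per-drug co-expression networks, hubs, communities, PPI overlap
  ppi <- if (!is.null(config$ppi_edges))
    import_edge_list(config$ppi_edges,
                     min_confidence = config$ppi_min_confidence) else NULL
  common_hubs <- list()
  hub_rows <- list()
  for (drug in names(deg_tables)) {
    deg <- deg_tables[[drug]]
    genes <- deg$gene[deg$pass]
    if (length(genes) < 2L) next
    d <- cls$calls[cls$calls$drug == drug & cls$calls$selected, , drop = FALSE]
    samples <- intersect(d$cell_line, colnames(expr))
    regulation <- setNames(deg$direction[deg$pass], genes)
    net <- build_coexpression_network(expr[, samples, drop = FALSE],
                                      gene_subset = genes, tau = config$tau,
                                      regulation = regulation)
    hubs <- select_hubs(net, top_fraction = config$hub_top_fraction,
                        drug = drug)
    part <- detect_communities(net)
    hub_rows[[drug]] <- data.frame(
      drug = drug, gene = names(hubs$degrees),
      degree = unname(hubs$degrees),
      is_hub = names(hubs$degrees) %in% hubs$hubs,
      community = unname(part$membership[names(hubs$degrees)]),
      stringsAsFactors = FALSE)
    if (!is.null(ppi)) {
      clusters <- split(names(part$membership), part$membership)
      ppi_hubs <- lapply(clusters, function(g) {
        sub <- igraph::induced_subgraph(
          ppi, intersect(g, igraph::V(ppi)$name))
        if (igraph::vcount(sub) == 0L) return(character(0))
        select_hubs(sub, top_fraction = config$hub_top_fraction,
                    drug = drug)$hubs
      })
      names(ppi_hubs) <- paste0("cluster", names(clusters))
      common_hubs[[drug]] <- intersect_hubs(hubs, ppi_hubs)
    } else {
      common_hubs[[drug]] <- list(all = hubs$hubs)
    }
  }
  if (length(hub_rows))
    write_tsv(do.call(rbind, hub_rows),
              file.path(config$out_dir, "coexpression_hubs.tsv"))
  report$stages$networks <- list(
    n_drugs_with_network = length(hub_rows),
    ppi_used = !is.null(ppi))

  # stage 5: common hubs across drugs
  shared <- NULL
  if (length(common_hubs) >= 2L) {
    shared <- common_across_drugs(common_hubs)
    write_tsv(shared, file.path(config$out_dir, "common_hubs_across_drugs.tsv"))
    report$stages$common_hubs <- list(n_genes = nrow(shared))
  }

  # stage 6: directed regulatory network and axis report
  axis <- NULL
  if (!is.null(config$reg_edges)) {
    edges <- read_tsv(config$reg_edges)
    net <- regulatory_network(edges)
    ct <- centrality_table(net)
    write_tsv(ct, file.path(config$out_dir, "centralities.tsv"))
    annot <- if (!is.null(config$transcripts))
      read_tsv(config$transcripts) else NULL
    sites <- if (!is.null(config$sites)) read_tsv(config$sites) else NULL
    axis <- build_axis_report(net, annot = annot, sites = sites)
    jsonlite::write_json(unclass(axis),
                         file.path(config$out_dir, "axis_report.json"),
                         auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA)
    report$stages$regulatory <- c(network_summary(net)[c("n_nodes",
                                                         "n_edges")],
                                  list(regulator = axis$regulator))
  }

  # stage 7: enrichment of the recurrent / passing genes
  if (!is.null(config$gmt)) {
    ann <- read_gmt(config$gmt)
    query <- if (!is.null(recurrent) && nrow(recurrent) > 0L) recurrent$gene
             else unique(unlist(lapply(deg_tables,
                                       function(d) d$gene[d$pass])))
    if (length(intersect(query, ann$universe))) {
      enr <- enrich(query, ann, fdr_cut = config$fdr_cut)
      write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
      report$stages$enrichment <- list(
        n_terms = nrow(enr), n_significant = sum(enr$significant),
        top_term = if (nrow(enr)) enr$term[1] else NA_character_)
    }
  }

  report$axis_report <- if (!is.null(axis)) unclass(axis) else NULL
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA, force = TRUE)
  class(report) <- "run_report"
  report
}
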