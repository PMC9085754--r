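#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror the
#' study conditions the pipeline was designed around: 41 cell lines screened
#' against 10 drugs, a bimodal LN_IC50 response (means +/- 2, sd 0.5), a
#' 1000-gene log2 expression matrix with 50 planted differentially expressed
#' genes at effect 3, and a tripartite regulatory network of 48 lncRNAs,
#' 38 transcription factors and 5 coding hub genes with one planted master
#' regulator of out-degree 8 against a background out-degree cap of 3.
#'
#' @param n_cell_lines number of cell lines (response-matrix rows).
#' @param n_drugs number of drugs (response-matrix columns).
#' @param frac_resistant_per_drug fraction of cell lines drawn from the
#'   resistant mode per drug, in (0, 1).
#' @param ic50_resistant_mean,ic50_sensitive_mean LN_IC50 means of the two
#'   response modes.
#' @param ic50_sd LN_IC50 standard deviation (shared by both modes).
#' @param n_genes,n_de_genes expression-matrix size and number of planted
#'   differentially expressed genes (`n_de_genes <= n_genes`).
#' @param de_effect_log2 planted shift, in log2 units, added to (half) or
#'   subtracted from (other half of) the planted genes in resistant samples.
#' @param expr_baseline_mean,expr_noise_sd baseline log2 expression level and
#'   Gaussian noise standard deviation.
#' @param n_lncRNA,n_TF,n_coding node-class sizes of the simulated regulatory
#'   network.
#' @param planted_regulator_outdegree out-degree of the planted master
#'   regulator; must exceed `background_max_outdegree`.
#' @param background_max_outdegree out-degree cap for every other source node.
#' @param plant_feedback_loop if `TRUE`, one TF target of the planted
#'   regulator carries an edge back to it (a mutual-interaction loop).
#' @param rng_seed integer seed; identical config + seed gives byte-identical
#'   outputs. Substreams are derived as `rng_seed + 0/1/2` for the response,
#'   expression and regulatory-network generators, in that order.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cell_lines = 41L,
                       n_drugs = 10L,
                       frac_resistant_per_drug = 0.5,
                       ic50_resistant_mean = 2,
                       ic50_sensitive_mean = -2,
                       ic50_sd = 0.5,
                       n_genes = 1000L,
                       n_de_genes = 50L,
                       de_effect_log2 = 3,
                       expr_baseline_mean = 7,
                       expr_noise_sd = 0.5,
                       n_lncRNA = 48L,
                       n_TF = 38L,
                       n_coding = 5L,
                       planted_regulator_outdegree = 8L,
                       background_max_outdegree = 3L,
                       plant_feedback_loop = TRUE,
                       rng_seed = 1L) {
  cfg <- list(
    n_cell_lines = as.integer(n_cell_lines),
    n_drugs = as.integer(n_drugs),
    frac_resistant_per_drug = frac_resistant_per_drug,
    ic50_resistant_mean = ic50_resistant_mean,
    ic50_sensitive_mean = ic50_sensitive_mean,
    ic50_sd = ic50_sd,
    n_genes = as.integer(n_genes),
    n_de_genes = as.integer(n_de_genes),
    de_effect_log2 = de_effect_log2,
    expr_baseline_mean = expr_baseline_mean,
    expr_noise_sd = expr_noise_sd,
    n_lncRNA = as.integer(n_lncRNA),
    n_TF = as.integer(n_TF),
    n_coding = as.integer(n_coding),
    planted_regulator_outdegree = as.integer(planted_regulator_outdegree),
    background_max_outdegree = as.integer(background_max_outdegree),
    plant_feedback_loop = isTRUE(plant_feedback_loop),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_cell_lines", "n_drugs", "n_genes", "n_lncRNA", "n_TF",
              "n_coding")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("sim_config: '", f, "' must be a positive count", call. = FALSE)
  }
  if (cfg$n_de_genes < 0L || cfg$n_de_genes > cfg$n_genes)
    stop("sim_config: n_de_genes must lie in [0, n_genes]", call. = FALSE)
  if (!is.finite(cfg$frac_resistant_per_drug) ||
      cfg$frac_resistant_per_drug <= 0 || cfg$frac_resistant_per_drug >= 1)
    stop("sim_config: frac_resistant_per_drug must lie in (0, 1)",
         call. = FALSE)
  if (cfg$ic50_sd < 0 || cfg$expr_noise_sd < 0)
    stop("sim_config: standard deviations must be non-negative",
         call. = FALSE)
  if (cfg$planted_regulator_outdegree > cfg$n_TF + cfg$n_coding)
    stop("sim_config: planted_regulator_outdegree exceeds available targets",
         call. = FALSE)
  if (cfg$planted_regulator_outdegree < 1L)
    stop("sim_config: planted_regulator_outdegree must be >= 1", call. = FALSE)
  if (cfg$background_max_outdegree >= cfg$planted_regulator_outdegree)
    stop("sim_config: background_max_outdegree must be smaller than ",
         "planted_regulator_outdegree", call. = FALSE)
  invisible(cfg)
}

#' Simulate a cell-line x drug LN_IC50 response matrix
#'
#' Per drug, `round(n_cell_lines * frac_resistant_per_drug)` cell lines are
#' drawn from `Normal(ic50_resistant_mean, ic50_sd)` and the remainder from
#' `Normal(ic50_sensitive_mean, ic50_sd)`. True class labels are emitted
#' alongside the values so downstream recovery can be audited.
#'
#' @param config a [sim_config()].
#' @return list with `values` (cell line x drug numeric matrix), `labels`
#'   (character matrix of the true classes, same dimnames) and `config`.
#' @export
simulate_drug_response <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  n <- config$n_cell_lines
  d <- config$n_drugs
  cells <- sprintf("cell_%03d", seq_len(n))
  drugs <- sprintf("drug_%02d", seq_len(d))
  values <- matrix(NA_real_, n, d, dimnames = list(cells, drugs))
  labels <- matrix(NA_character_, n, d, dimnames = list(cells, drugs))
  n_res <- as.integer(round(n * config$frac_resistant_per_drug))
  for (j in seq_len(d)) {
    res_idx <- sample.int(n, n_res)
    lab <- rep("sensitive", n)
    lab[res_idx] <- "resistant"
    mu <- ifelse(lab == "resistant",
                 config$ic50_resistant_mean, config$ic50_sensitive_mean)
    values[, j] <- rnorm(n, mean = mu, sd = config$ic50_sd)
    labels[, j] <- lab
  }
  list(values = values, labels = labels, config = config)
}

#' Simulate a gene x sample log2 expression matrix with planted DE genes
#'
#' Background genes are `Normal(expr_baseline_mean, expr_noise_sd)` in every
#' sample. A planted subset of `n_de_genes` genes is shifted in resistant
#' samples by `+de_effect_log2` (first half, "up") or `-de_effect_log2`
#' (second half, "down").
#'
#' @param config a [sim_config()].
#' @param class_labels named character vector mapping sample id to
#'   `"sensitive"` or `"resistant"`; its names define the sample columns.
#' @return list with `values` (gene x sample matrix), `sample_class` (the
#'   input labels), and `planted` (data.frame of planted gene, direction).
#' @export
simulate_expression <- function(config, class_labels) {
  validate_sim_config(config)
  if (is.null(names(class_labels)) || anyDuplicated(names(class_labels)))
    stop("class_labels must be uniquely named by sample id", call. = FALSE)
  if (!all(class_labels %in% c("sensitive", "resistant")))
    stop("class_labels values must be 'sensitive' or 'resistant'",
         call. = FALSE)
  set.seed(config$rng_seed + 1L)
  samples <- names(class_labels)
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  values <- matrix(
    rnorm(config$n_genes * length(samples),
          mean = config$expr_baseline_mean, sd = config$expr_noise_sd),
    nrow = config$n_genes,
    dimnames = list(genes, samples)
  )
  planted <- data.frame(gene = character(0), direction = character(0),
                        stringsAsFactors = FALSE)
  if (config$n_de_genes > 0L) {
    de_genes <- sort(sample(genes, config$n_de_genes))
    n_up <- ceiling(config$n_de_genes / 2)
    direction <- rep(c("up", "down"),
                     c(n_up, config$n_de_genes - n_up))
    res_cols <- which(class_labels == "resistant")
    shift <- ifelse(direction == "up", 1, -1) * config$de_effect_log2
    values[de_genes, res_cols] <- values[de_genes, res_cols] + shift
    planted <- data.frame(gene = de_genes, direction = direction,
                          stringsAsFactors = FALSE)
  }
  list(values = values, sample_class = class_labels, planted = planted)
}

#' Simulate a directed lncRNA-TF-coding regulatory network
#'
#' Builds a tripartite directed network in which edges run only
#' lncRNA -> \{TF, coding\} and TF -> \{coding, lncRNA\} (coding genes are
#' sinks). One planted lncRNA receives out-degree
#' `planted_regulator_outdegree` with at least one TF target; every other
#' source node has out-degree at most `background_max_outdegree`. If
#' `plant_feedback_loop` is `TRUE`, the planted regulator's first TF target
#' carries an edge back to it, and that is the only mutual pair in the
#' network.
#'
#' @param config a [sim_config()].
#' @return list with `network` (a directed [igraph][igraph::igraph-package]
#'   graph with vertex attribute `class`), `edges` (data.frame `source`,
#'   `target`, `source_class`, `target_class`, `provenance`), `nodes`
#'   (data.frame `node`, `class`), `planted_regulator`, and `feedback_pair`
#'   (character 2-vector TF, lncRNA; `NULL` if not planted).
#' @export
simulate_regulatory_network <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed + 2L)
  lnc <- sprintf("lnc_%02d", seq_len(config$n_lncRNA))
  tfs <- sprintf("TF_%02d", seq_len(config$n_TF))
  coding <- sprintf("gene_%02d", seq_len(config$n_coding))
  node_class <- c(setNames(rep("lncRNA", length(lnc)), lnc),
                  setNames(rep("TF", length(tfs)), tfs),
                  setNames(rep("coding", length(coding)), coding))

  planted <- lnc[1]
  k <- config$planted_regulator_outdegree
  pool <- c(tfs, coding)
  # guarantee >=1 TF target: always include the first TF
  extra <- setdiff(pool, tfs[1])
  planted_targets <- c(tfs[1],
                       if (k > 1L) sample(extra, k - 1L) else character(0))
  edges <- data.frame(source = planted, target = planted_targets,
                      stringsAsFactors = FALSE)

  bg <- config$background_max_outdegree
  for (src in lnc[-1]) {
    d <- sample.int(bg + 1L, 1L) - 1L            # 0..bg
    if (d > 0L)
      edges <- rbind(edges, data.frame(source = src,
                                       target = sample(pool, d),
                                       stringsAsFactors = FALSE))
  }
  # TF targets: coding genes and lncRNAs, excluding lncRNAs that already
  # target this TF (keeps the planted loop the unique mutual pair)
  feedback_pair <- NULL
  for (tf in tfs) {
    incoming_lnc <- edges$source[edges$target == tf]
    tf_pool <- c(coding, setdiff(lnc, incoming_lnc))
    cap <- bg
    if (config$plant_feedback_loop && tf == tfs[1]) cap <- max(bg - 1L, 0L)
    d <- if (cap > 0L) sample.int(cap + 1L, 1L) - 1L else 0L
    d <- min(d, length(tf_pool))
    if (d > 0L)
      edges <- rbind(edges, data.frame(source = tf,
                                       target = sample(tf_pool, d),
                                       stringsAsFactors = FALSE))
  }
  if (config$plant_feedback_loop) {
    edges <- rbind(edges, data.frame(source = tfs[1], target = planted,
                                     stringsAsFactors = FALSE))
    feedback_pair <- c(tfs[1], planted)
  }
  edges <- unique(edges)
  edges$source_class <- unname(node_class[edges$source])
  edges$target_class <- unname(node_class[edges$target])
  edges$provenance <- "simulated"
  nodes <- data.frame(node = names(node_class), class = unname(node_class),
                      stringsAsFactors = FALSE)
  net <- regulatory_network(edges, nodes = nodes)
  list(network = net, edges = edges, nodes = nodes,
       planted_regulator = planted, feedback_pair = feedback_pair)
}

#' Simulate a GMT-style annotation set
#'
#' Random gene-set terms over a gene universe, optionally with one planted
#' term that contains a supplied gene set (plus random padding), for testing
#' the enrichment stage.
#'
#' @param genes character vector, the gene universe.
#' @param n_terms number of random terms.
#' @param term_size_range length-2 integer vector, inclusive term-size range.
#' @param enriched_term optional `list(name =, genes =)`; the planted term.
#' @param rng_seed integer seed.
#' @return an `annotation_set`: list with `terms` (named list of gene
#'   vectors), `descriptions`, and `universe`.
#' @export
simulate_annotations <- function(genes, n_terms,
                                 term_size_range = c(5L, 25L),
                                 enriched_term = NULL, rng_seed = 1L) {
  if (length(genes) == 0L) stop("empty gene universe", call. = FALSE)
  if (max(term_size_range) > length(genes))
    stop("term sizes exceed the gene universe", call. = FALSE)
  set.seed(as.integer(rng_seed))
  terms <- list()
  if (n_terms > 0L) {
    size_pool <- seq(term_size_range[1], term_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_terms,
                                  replace = TRUE)]
    terms <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(terms) <- sprintf("term_%03d", seq_len(n_terms))
  }
  if (!is.null(enriched_term)) {
    base <- intersect(enriched_term$genes, genes)
    pad_n <- max(0L, term_size_range[1] - length(base))
    pad <- if (pad_n > 0L) sample(setdiff(genes, base), pad_n) else character(0)
    terms[[enriched_term$name]] <- sort(c(base, pad))
  }
  annotation_set(terms, universe = genes)
}

#' Simulate transcript structure annotation
#'
#' Assigns each gene a chromosome and a contiguous 1-based inclusive
#' transcript model (5'UTR, CDS, 3'UTR). Genes in `co_located_genes` are
#' forced onto `regulator_chromosome`; all other genes are placed on a
#' different chromosome, so cis/trans calls against the regulator are
#' unambiguous by construction.
#'
#' @param genes character vector of gene ids.
#' @param n_chromosomes number of chromosomes `chr1..chrN` to draw from.
#' @param regulator_chromosome chromosome id of the regulator (e.g. "chr11").
#' @param co_located_genes subset of `genes` to co-locate with the regulator.
#' @param rng_seed integer seed.
#' @return data.frame with columns `gene`, `chrom`, `utr5_start`, `utr5_end`,
#'   `cds_start`, `cds_end`, `utr3_start`, `utr3_end`.
#' @export
simulate_transcript_annotation <- function(genes, n_chromosomes = 23L,
                                           regulator_chromosome = "chr11",
                                           co_located_genes = character(0),
                                           rng_seed = 1L) {
  if (!all(co_located_genes %in% genes))
    stop("co_located_genes must be a subset of genes", call. = FALSE)
  set.seed(as.integer(rng_seed))
  chroms <- sprintf("chr%d", seq_len(n_chromosomes))
  other <- setdiff(chroms, regulator_chromosome)
  if (length(other) == 0L)
    stop("need at least one chromosome besides the regulator's",
         call. = FALSE)
  chrom <- sample(other, length(genes), replace = TRUE)
  names(chrom) <- genes
  chrom[co_located_genes] <- regulator_chromosome
  utr5_len <- sample(50:300, length(genes), replace = TRUE)
  cds_len <- sample(300:3000, length(genes), replace = TRUE)
  utr3_len <- sample(100:1000, length(genes), replace = TRUE)
  data.frame(
    gene = genes,
    chrom = unname(chrom),
    utr5_start = 1L,
    utr5_end = utr5_len,
    cds_start = utr5_len + 1L,
    cds_end = utr5_len + cds_len,
    utr3_start = utr5_len + cds_len + 1L,
    utr3_end = utr5_len + cds_len + utr3_len,
    stringsAsFactors = FALSE
  )
}

#' Simulate every pipeline input as files
#'
#' Runs the individual generators in documented order (response, expression
#' against drug 1's true labels, regulatory network, annotations, transcripts,
#' interaction sites) and writes the standard TSV/GMT inputs consumed by
#' [run_all()] to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the planted truth
#'   (`labels`, `planted_genes`, `planted_regulator`).
#' @export
simulate_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resp <- simulate_drug_response(config)
  labels <- setNames(resp$labels[, 1], rownames(resp$labels))
  expr <- simulate_expression(config, labels)
  reg <- simulate_regulatory_network(config)
  ann <- simulate_annotations(rownames(expr$values), n_terms = 20L,
                              enriched_term = list(name = "planted_term",
                                                   genes = expr$planted$gene),
                              rng_seed = config$rng_seed + 3L)
  drivers <- reg$nodes$node[reg$nodes$class == "coding"]
  annot <- simulate_transcript_annotation(
    c(reg$planted_regulator, drivers),
    co_located_genes = drivers[1],
    rng_seed = config$rng_seed + 4L
  )
  sites <- data.frame(
    lncRNA = reg$planted_regulator,
    target = drivers,
    start = 5L,
    end = 25L,
    stringsAsFactors = FALSE
  )
  paths <- list(
    response = file.path(out_dir, "response.tsv"),
    truth_labels = file.path(out_dir, "truth_labels.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    reg_edges = file.path(out_dir, "reg_edges.tsv"),
    gmt = file.path(out_dir, "annotations.gmt"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    sites = file.path(out_dir, "sites.tsv")
  )
  write_matrix_tsv(resp$values, paths$response)
  write_matrix_tsv(resp$labels, paths$truth_labels)
  write_matrix_tsv(expr$values, paths$expression)
  write_tsv(reg$edges, paths$reg_edges)
  write_gmt(ann, paths$gmt)
  write_tsv(annot, paths$transcripts)
  write_tsv(sites, paths$sites)
  invisible(c(paths, list(labels = labels,
                          planted_genes = expr$planted,
                          planted_regulator = reg$planted_regulator)))
}
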