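# Worked-example fixtures: a curated MALAT1/EGR1 regulatory subnetwork and
# the per-drug common-hub gene sets reported for five kinase inhibitors in
# the pan-cancer multi-drug-resistance literature. These small tables are the
# package's standing worked example; tests and the acceptance script replay
# the analysis on them.

#' Worked-example directed regulatory edge table
#'
#' A curated subnetwork around the lncRNA MALAT1, the transcription factor
#' EGR1 and the five coding driver genes FN1, CD44, TIMP1, SNAI2 and SPARC:
#' MALAT1 directly regulates SPARC, SNAI2 and six transcription factors
#' (EGR1 plus five placeholders, `TF_B`..`TF_F`, whose identities are not
#' published); EGR1 regulates FN1, CD44, TIMP1 and MALAT1 (the
#' EGR1-MALAT1 feedback loop); YBX1 regulates CD44, FN1, SPARC and TIMP1;
#' AR regulates CD44, FN1 and SPARC. Additional lncRNAs (HOTAIR, H19,
#' lincRNA-p21, SLNCR) and TFs (NFKB1, FOS, ETS1, HIF1A, TP53, SP1, CTNNB1)
#' carry placeholder targets reproducing their reported out-degrees where
#' stated.
#'
#' @return data.frame with columns `source`, `target`, `source_class`,
#'   `target_class`, `provenance`, suitable for [regulatory_network()].
#' @export
example_regulatory_edges <- function() {
  edge <- function(source, target, source_class, target_class,
                   provenance = "curated") {
    data.frame(source = source, target = target,
               source_class = source_class, target_class = target_class,
               provenance = provenance, stringsAsFactors = FALSE)
  }
  placeholder_tfs <- c("TF_B", "TF_C", "TF_D", "TF_E", "TF_F")
  rbind(
    # MALAT1 -> 2 coding hubs + 6 TFs (out-degree 8)
    edge("MALAT1", c("SPARC", "SNAI2"), "lncRNA", "coding", "text-mined"),
    edge("MALAT1", c("EGR1", placeholder_tfs), "lncRNA", "TF", "text-mined"),
    # EGR1 -> 3 coding hubs + MALAT1 (out-degree 4; the feedback edge)
    edge("EGR1", c("FN1", "CD44", "TIMP1"), "TF", "coding", "ChIP"),
    edge("EGR1", "MALAT1", "TF", "lncRNA", "ChIP"),
    # YBX1 -> 4 coding hubs
    edge("YBX1", c("CD44", "FN1", "SPARC", "TIMP1"), "TF", "coding",
         "curated"),
    # AR -> 3 stated coding hubs
    edge("AR", c("CD44", "FN1", "SPARC"), "TF", "coding", "curated"),
    # TFs with reported out-degree 3 (placeholder target identities)
    edge("NFKB1", c("CD44", "FN1", "TIMP1"), "TF", "coding", "predicted"),
    edge("FOS", c("FN1", "SPARC", "SNAI2"), "TF", "coding", "predicted"),
    edge("ETS1", c("CD44", "TIMP1", "SNAI2"), "TF", "coding", "predicted"),
    # HIF1A reported out-degree 2
    edge("HIF1A", c("SPARC", "SNAI2"), "TF", "coding", "predicted"),
    edge("TP53", c("CD44", "FN1"), "TF", "coding", "predicted"),
    edge("SP1", "TIMP1", "TF", "coding", "predicted"),
    edge("CTNNB1", "SNAI2", "TF", "coding", "predicted"),
    # lncRNAs with reported out-degree 3 (placeholder TF targets; these TFs
    # have no coding out-edges, so indirect regulation stays via EGR1 only)
    edge("HOTAIR", c("TF_B", "TF_C", "TF_D"), "lncRNA", "TF", "text-mined"),
    edge("H19", c("TF_C", "TF_D", "TF_E"), "lncRNA", "TF", "text-mined"),
    edge("lincRNA-p21", c("TF_E", "TF_F"), "lncRNA", "TF", "text-mined"),
    edge("SLNCR", "TF_F", "lncRNA", "TF", "text-mined")
  )
}

#' Worked-example transcript annotation for the regulatory axis
#'
#' Chromosome assignments of MALAT1 and its five coding driver targets
#' (MALAT1 and CD44 share chromosome 11; FN1, TIMP1, SNAI2 and SPARC lie on
#' chromosomes 2, X, 8 and 5) with synthetic but structurally valid
#' transcript models (contiguous 1-based 5'UTR / CDS / 3'UTR intervals).
#'
#' @return transcript annotation data.frame (same layout as
#'   [simulate_transcript_annotation()]).
#' @export
example_transcript_annotation <- function() {
  tx <- function(gene, chrom, u5, cds, u3) {
    data.frame(gene = gene, chrom = chrom,
               utr5_start = 1L, utr5_end = u5,
               cds_start = u5 + 1L, cds_end = u5 + cds,
               utr3_start = u5 + cds + 1L, utr3_end = u5 + cds + u3,
               stringsAsFactors = FALSE)
  }
  rbind(
    tx("MALAT1", "chr11", 100L, 6000L, 2000L),
    tx("CD44",   "chr11", 150L, 2200L, 3000L),
    tx("FN1",    "chr2",  250L, 7000L, 1200L),
    tx("TIMP1",  "chrX",  80L,  600L,  300L),
    tx("SNAI2",  "chr8",  120L, 800L,  1500L),
    tx("SPARC",  "chr5",  90L,  900L,  1100L)
  )
}

#' Worked-example lncRNA-mRNA interaction sites
#'
#' Predicted MALAT1 binding sites on its five coding driver targets, placed
#' in the regions reported for each pair: FN1 in the 5'UTR, TIMP1 and SNAI2
#' in the CDS, CD44 and SPARC in the 3'UTR (coordinates are synthetic, the
#' region placement is the point).
#'
#' @return data.frame `lncRNA`, `target`, `start`, `end` (1-based inclusive
#'   mRNA coordinates on the target transcript).
#' @export
example_interaction_sites <- function() {
  data.frame(
    lncRNA = "MALAT1",
    target = c("FN1", "TIMP1", "SNAI2", "CD44", "SPARC"),
    start = c(40L, 300L, 400L, 2600L, 1200L),
    end = c(90L, 360L, 470L, 2680L, 1290L),
    stringsAsFactors = FALSE
  )
}

#' Worked-example per-drug common-hub gene sets
#'
#' The genes shared between each drug's co-expression hub list and its
#' per-cluster PPI hub lists, as published for the five analyzable kinase
#' inhibitors (clusters with no common hubs are `NA`).
#'
#' @return named list (drug -> named list of cluster -> character vector or
#'   `NA`).
#' @export
example_common_hub_sets <- function() {
  list(
    Ponatinib = list(
      cluster1 = NA_character_,
      cluster2 = c("TYR", "PMEL", "MLANA", "EDNRB"),
      cluster3 = c("FN1", "CD44", "MMP1", "TIMP1", "MMP14", "SPARC",
                   "SNAI2", "VEGFC", "TIMP3")
    ),
    Foretinib = list(
      cluster2 = c("FN1", "TIMP1", "CD44")
    ),
    Selumetinib = list(
      cluster2 = c("LCP2", "FYB", "IL7R", "CD38"),
      cluster3 = c("FN1", "CD44", "TIMP1", "CCND1", "CAV1", "PTGS2",
                   "SNAI2", "LGALS1")
    ),
    Trametinib = list(
      cluster1 = c("CD44", "CCL2", "ANXA1", "AHR"),
      cluster2 = c("FN1", "SPARC", "CYR61", "CTGF", "ITGB5", "LAMC1",
                   "TGFB1")
    ),
    `CI-1040` = list(
      cluster2 = c("KRT7", "KRT8", "KRT19", "EPCAM")
    )
  )
}
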