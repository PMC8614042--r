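#' Shannon entropy of junction usage within an intron cluster
#'
#' For a cluster with m junctions carrying read counts n_k, the usage
#' fractions are f_k = n_k / sum(n_k) and the entropy is
#' H = -sum f_k log2 f_k (bits), with 0 * log 0 taken as 0. H ranges from 0
#' (one junction carries all reads) to log2(m) (uniform usage).
#'
#' @param counts Non-empty numeric vector of non-negative junction read
#'   counts with a positive sum.
#' @return Entropy in bits.
#' @export
cluster_entropy <- function(counts) {
  if (!length(counts)) stop("empty count vector")
  if (any(counts < 0)) stop("negative junction count")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector: entropy undefined")
  f <- counts / tot
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Gene-level ASL: summed entropy over a gene's intron clusters
#'
#' @param record A single-gene row of a splicing-record table, or a list with
#'   a `cluster_entropies` numeric vector.
#' @return Sum of cluster entropies; 0 for a gene with no clusters.
#' @export
gene_asl_junction <- function(record) {
  h <- record$cluster_entropies
  if (is.null(h) || !length(h)) return(0)
  sum(h)
}

#' Count splicing events passing the read-support filter
#'
#' @param event_reads Numeric vector of per-event supporting read counts.
#' @param min_reads Minimum supporting reads for an event to count
#'   (default 5).
#' @return Integer number of supported events.
#' @export
n_supported_events <- function(event_reads, min_reads = 5) {
  if (!length(event_reads)) return(0L)
  sum(event_reads >= min_reads)
}

#' Build per-gene splicing records (junction mode)
#'
#' Joins the annotation, gene-assigned intron clusters and a coverage track
#' into the per-gene table that ASP/ASL and the binning correction operate
#' on. `expression` is the maximum exonic coverage depth; `is_expressed`
#' applies the strict `depth > min_depth` rule; `entropy_asl` is the summed
#' Shannon entropy of the gene's clusters.
#'
#' @param annotation A `genome_annotation`.
#' @param clusters Gene-assigned `intron_clusters`
#'   (see [assign_and_filter_clusters()]).
#' @param coverage Coverage data.frame, or NULL if `expression` is given.
#' @param expression Optional precomputed data.frame (gene_id, expression)
#'   used instead of a coverage track.
#' @param min_depth Strict expression threshold (default 2).
#' @return data.frame with gene_id, expression, is_multi_exon, is_expressed,
#'   n_clusters, entropy_asl, n_isoforms, n_events.
#' @export
gene_splicing_records <- function(annotation, clusters, coverage = NULL,
                                  expression = NULL, min_depth = 2) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(clusters, "intron_clusters"))
  tab <- gene_intron_table(annotation)
  if (is.null(expression)) {
    if (is.null(coverage)) stop("provide coverage or expression")
    expression <- gene_expression_from_coverage(annotation, coverage,
                                                min_depth)[, c("gene_id", "expression")]
  }
  rec <- data.frame(gene_id = tab$gene_id, stringsAsFactors = FALSE)
  rec$expression <- expression$expression[match(rec$gene_id,
                                                expression$gene_id)]
  rec$expression[is.na(rec$expression)] <- 0
  rec$is_multi_exon <- tab$is_multi_exon
  rec$is_expressed <- rec$expression > min_depth

  j <- clusters$junctions
  cl <- clusters$clusters
  if (nrow(cl)) {
    ## entropy per cluster from its junction counts, summed per gene
    h <- vapply(split(j$count, j$cluster_id), cluster_entropy, numeric(1))
    gene_of <- stats::setNames(cl$gene_id, cl$cluster_id)
    h_by_gene <- rowsum(unname(h), unname(gene_of[names(h)]))
    n_by_gene <- table(unname(gene_of[names(h)]))
    idx <- match(rec$gene_id, rownames(h_by_gene))
    rec$n_clusters <- ifelse(is.na(n_by_gene[rec$gene_id]), 0L,
                             as.integer(n_by_gene[rec$gene_id]))
    rec$entropy_asl <- ifelse(is.na(idx), 0, h_by_gene[idx, 1])
  } else {
    rec$n_clusters <- 0L
    rec$entropy_asl <- 0
  }
  ## isoform count from the annotation (junction mode carries it along)
  n_iso <- table(annotation$transcripts$gene_id)
  rec$n_isoforms <- as.integer(n_iso[rec$gene_id])
  rec$n_events <- NA_integer_
  rec
}

.asp_denominator <- function(records, mode, fpkm_threshold) {
  if (mode == "junction") {
    records$is_multi_exon & records$is_expressed
  } else {
    records$is_multi_exon & records$expression > fpkm_threshold
  }
}

#' Species-level alternative splicing prevalence (ASP)
#'
#' The fraction of expressed multi-exon genes showing alternative splicing,
#' under three counting modes: `junction` (at least one intron cluster, with
#' expression = max exonic depth and the strict `> min_depth` rule already
#' encoded in `is_expressed`), `isoform` (more than one annotated/assembled
#' isoform, expression FPKM strictly above `fpkm_threshold`) and `event`
#' (more than one supported splicing event, same FPKM rule; event support
#' filtering happens upstream, see [n_supported_events()]).
#'
#' @param records Per-gene record table (see [gene_splicing_records()]).
#' @param mode `"junction"`, `"isoform"` or `"event"`.
#' @param fpkm_threshold Expression threshold for isoform/event modes
#'   (default 0.1, strict `>`).
#' @return ASP in \[0, 1\].
#' @export
species_asp <- function(records, mode = c("junction", "isoform", "event"),
                        fpkm_threshold = 0.1) {
  mode <- match.arg(mode)
  denom <- .asp_denominator(records, mode, fpkm_threshold)
  if (!any(denom)) stop("no expressed multi-exon genes")
  num <- switch(mode,
    junction = records$n_clusters[denom] >= 1L,
    isoform = records$n_isoforms[denom] > 1L,
    event = records$n_events[denom] > 1L)
  mean(num)
}

#' Species-level alternative splicing level (ASL)
#'
#' Mean of the per-gene splicing quantity over expressed multi-exon genes:
#' summed cluster entropy (junction mode; genes with no clusters enter as
#' zeros), isoform count (isoform mode) or supported event count (event
#' mode).
#'
#' @inheritParams species_asp
#' @return Non-negative ASL.
#' @export
species_asl <- function(records, mode = c("junction", "isoform", "event"),
                        fpkm_threshold = 0.1) {
  mode <- match.arg(mode)
  denom <- .asp_denominator(records, mode, fpkm_threshold)
  if (!any(denom)) stop("no expressed multi-exon genes")
  val <- switch(mode,
    junction = records$entropy_asl[denom],
    isoform = records$n_isoforms[denom],
    event = records$n_events[denom])
  mean(val)
}

#' Species splicing summary
#'
#' @inheritParams species_asp
#' @param species_id Species label carried into the output.
#' @return data.frame row: species_id, mode, asp, asl, n_genes_used.
#' @export
species_splicing_summary <- function(records, species_id = NA_character_,
                                     mode = "junction",
                                     fpkm_threshold = 0.1) {
  denom <- .asp_denominator(records, mode, fpkm_threshold)
  data.frame(species_id = species_id, mode = mode,
             asp = species_asp(records, mode, fpkm_threshold),
             asl = species_asl(records, mode, fpkm_threshold),
             n_genes_used = sum(denom), stringsAsFactors = FALSE)
}
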