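#' Read a bedGraph coverage track
#'
#' Four tab-separated columns: chrom, start (0-based), end (exclusive),
#' depth. Track/browser header lines are skipped.
#'
#' @param path Path to the bedGraph file.
#' @return data.frame with columns chrom, start, end, depth.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  raw <- utils::read.table(text = lines[keep], sep = "\t", header = FALSE)
  if (ncol(raw) < 4L) stop("bedGraph must have 4 columns: ", path)
  cov <- data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
                    end = as.integer(raw[[3]]), depth = as.numeric(raw[[4]]),
                    stringsAsFactors = FALSE)
  stopifnot(all(cov$start < cov$end), all(cov$depth >= 0))
  cov
}

#' Write a coverage track as bedGraph
#' @param coverage data.frame with chrom, start, end, depth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  utils::write.table(coverage[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Expression proxy: maximum coverage depth over a gene's exons
#'
#' The per-gene expression level is approximated as the maximum per-base
#' coverage depth over the union of the gene's exon intervals. Intronic
#' coverage is ignored.
#'
#' @param coverage Coverage data.frame (see [read_bedgraph()]).
#' @param gene A `gene_model`.
#' @return Maximum exonic depth; 0 when the gene's exons are uncovered (with
#'   a warning when the chromosome is absent from the track).
#' @export
approximate_expression <- function(coverage, gene) {
  stopifnot(inherits(gene, "gene_model"))
  cov <- coverage[coverage$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(cov)) {
    warning("chromosome ", gene$chrom, " absent from coverage track")
    return(0)
  }
  ex <- .reduce_intervals(do.call(rbind, lapply(gene$transcripts, `[[`, "exons")))
  hit <- rep(FALSE, nrow(cov))
  for (i in seq_len(nrow(ex)))
    hit <- hit | (cov$start < ex[i, "end"] & cov$end > ex[i, "start"])
  if (!any(hit)) return(0)
  max(cov$depth[hit])
}

#' Expressed multi-exon flag
#'
#' A gene counts as an expressed multi-exon gene when its representative
#' transcript has at least two exons and at least one exonic base has
#' coverage depth strictly greater than `min_depth`.
#'
#' @param gene A `gene_model`.
#' @param coverage Coverage data.frame.
#' @param min_depth Strict depth threshold (default 2).
#' @return Logical.
#' @export
expressed_multiexon_flag <- function(gene, coverage, min_depth = 2) {
  lens <- vapply(gene$transcripts,
                 function(t) nrow(t$exons), integer(1))
  exl <- vapply(gene$transcripts,
                function(t) sum(t$exons[, "end"] - t$exons[, "start"]),
                numeric(1))
  best <- sort(names(gene$transcripts)[exl == max(exl)])[1]
  if (lens[[best]] < 2L) return(FALSE)
  suppressWarnings(approximate_expression(coverage, gene)) > min_depth
}

#' Per-gene expression and expressed flags for a whole annotation
#'
#' Vectorised equivalent of [approximate_expression()] over all genes:
#' maximum exonic coverage depth per gene, plus the strict
#' `depth > min_depth` expressed flag.
#'
#' @param annotation A `genome_annotation`.
#' @param coverage Coverage data.frame.
#' @param min_depth Strict depth threshold (default 2).
#' @return data.frame with gene_id, expression, covered (logical).
#' @export
gene_expression_from_coverage <- function(annotation, coverage, min_depth = 2) {
  ex <- annotation$exons
  eg <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  cg <- GenomicRanges::GRanges(coverage$chrom,
                               IRanges::IRanges(coverage$start + 1L,
                                                coverage$end))
  hits <- GenomicRanges::findOverlaps(eg, cg, ignore.strand = TRUE)
  gid <- ex$gene_id[S4Vectors::queryHits(hits)]
  dep <- coverage$depth[S4Vectors::subjectHits(hits)]
  mx <- if (length(gid)) tapply(dep, gid, max) else numeric(0)
  out <- data.frame(gene_id = annotation$genes$gene_id,
                    stringsAsFactors = FALSE)
  out$expression <- ifelse(is.na(mx[out$gene_id]), 0,
                           as.numeric(mx[out$gene_id]))
  out$covered <- out$expression > min_depth
  out
}
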