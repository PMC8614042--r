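# Small hand-built fixtures, constructed in code at test time.

# Three-gene annotation exercising multi-transcript genes, CDS placement and
# single-exon genes. Coordinates are 0-based half-open.
demo_annotation <- function() {
  exons <- rbind(
    # geneA (+): t1 has 3 exons, t2 skips the middle exon
    data.frame(transcript_id = "tA1", gene_id = "geneA", chrom = "chr1",
               strand = "+",
               start = c(100, 300, 600), end = c(200, 400, 700)),
    data.frame(transcript_id = "tA2", gene_id = "geneA", chrom = "chr1",
               strand = "+", start = c(100, 600), end = c(200, 700)),
    # geneB (-): single exon
    data.frame(transcript_id = "tB1", gene_id = "geneB", chrom = "chr1",
               strand = "-", start = 2000, end = 2500),
    # geneC (+): two exons on another chromosome
    data.frame(transcript_id = "tC1", gene_id = "geneC", chrom = "chr2",
               strand = "+", start = c(0, 500), end = c(100, 900)))
  cds <- rbind(
    data.frame(transcript_id = "tA1", gene_id = "geneA", chrom = "chr1",
               strand = "+", start = c(120, 300, 600), end = c(200, 400, 650)),
    data.frame(transcript_id = "tA2", gene_id = "geneA", chrom = "chr1",
               strand = "+", start = c(120, 600), end = c(200, 650)),
    data.frame(transcript_id = "tC1", gene_id = "geneC", chrom = "chr2",
               strand = "+", start = c(10, 500), end = c(100, 800)))
  ann <- spliceprev:::.build_annotation(exons = exons, cds = cds)
  ann$source_format <- "fixture"
  ann
}

# Junction table builder
jx <- function(chrom, start, end, count, strand = "+",
               name = sprintf("j%d", seq_along(start))) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             count = count, strand = strand, stringsAsFactors = FALSE)
}

# Minimal per-gene record table for metric tests
rec_table <- function(expression, is_multi_exon, is_expressed = expression > 2,
                      n_clusters = 0L, entropy_asl = 0,
                      n_isoforms = NA_integer_, n_events = NA_integer_) {
  n <- max(length(expression), length(is_multi_exon), length(n_clusters),
           length(entropy_asl), length(n_isoforms), length(n_events))
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             expression = rep_len(expression, n),
             is_multi_exon = rep_len(is_multi_exon, n),
             is_expressed = rep_len(is_expressed, n),
             n_clusters = rep_len(n_clusters, n),
             entropy_asl = rep_len(entropy_asl, n),
             n_isoforms = rep_len(n_isoforms, n),
             n_events = rep_len(n_events, n), stringsAsFactors = FALSE)
}

# Bin series from raw response values (one observation per bin)
fake_series <- function(asp, asl = asp, bin_size = 500) {
  s <- data.frame(bin_index = seq_along(asp),
                  mean_expression = seq_along(asp), asp = asp, asl = asl,
                  n_genes = bin_size)
  attr(s, "bin_size") <- bin_size
  attr(s, "mode") <- "junction"
  class(s) <- c("bin_series", "data.frame")
  s
}

# Brute-force connected components by exhaustive pairwise shared-coordinate
# testing (independent oracle for cluster_junctions)
brute_components <- function(j) {
  n <- nrow(j)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (lab[a] != lab[b] && j$chrom[a] == j$chrom[b] &&
          j$strand[a] == j$strand[b] &&
          (j$start[a] == j$start[b] || j$end[a] == j$end[b])) {
        lab[lab == max(lab[a], lab[b])] <- min(lab[a], lab[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# Canonical signature of a clustering: sorted per-cluster junction key sets
cluster_signature <- function(cl) {
  keys <- split(paste(cl$junctions$chrom, cl$junctions$start,
                      cl$junctions$end, cl$junctions$strand),
                cl$junctions$cluster_id)
  sort(vapply(keys, function(k) paste(sort(k), collapse = "|"),
              character(1)), method = "radix")
}
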