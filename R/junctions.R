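#' Read a junction ("junc") file
#'
#' Six-column tab-separated BED-like format: chrom, intron start (0-based),
#' intron end (exclusive), name, read count, strand. Coordinates denote the
#' excised intron interval. Duplicate (chrom, start, end, strand) keys within
#' one file are summed with a warning.
#'
#' @param path Path to the file.
#' @return data.frame with columns chrom, start, end, name, count, strand.
#' @export
read_junction_file <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 6L) stop("junction file must have 6 columns: ", path)
  j <- data.frame(chrom = raw[[1]], start = suppressWarnings(as.numeric(raw[[2]])),
                  end = suppressWarnings(as.numeric(raw[[3]])), name = raw[[4]],
                  count = suppressWarnings(as.numeric(raw[[5]])),
                  strand = raw[[6]], stringsAsFactors = FALSE)
  bad <- which(is.na(j$start) | is.na(j$end) | is.na(j$count) |
                 j$start >= j$end | j$count < 0 | j$count != floor(j$count))
  if (length(bad))
    stop("malformed junction record at line ", bad[1], " of ", path)
  j$start <- as.integer(j$start); j$end <- as.integer(j$end)
  j$count <- as.integer(j$count)
  key <- paste(j$chrom, j$start, j$end, j$strand, sep = ":")
  if (anyDuplicated(key)) {
    warning("duplicate junction keys in ", path, ": counts summed")
    j <- merge_junction_sets(list(j))
  }
  validate_junctions(j)
}

#' @keywords internal
validate_junctions <- function(j) {
  stopifnot(is.data.frame(j),
            all(c("chrom", "start", "end", "count", "strand") %in% names(j)))
  if (is.null(j$name)) j$name <- sprintf("j%d", seq_len(nrow(j)))
  stopifnot(all(j$start < j$end), all(j$count >= 0),
            all(j$strand %in% c("+", "-", ".")))
  j[, c("chrom", "start", "end", "name", "count", "strand")]
}

#' Write junctions in the 6-column junc format
#' @param junctions Junction data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_file <- function(junctions, path) {
  j <- validate_junctions(junctions)
  utils::write.table(j, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge junction sets, summing read support
#'
#' Union over (chrom, start, end, strand) keys across samples; read counts
#' supporting the same junction are summed.
#'
#' @param sets List of junction data.frames.
#' @return One junction data.frame, sorted by chrom, start, end, strand.
#' @export
merge_junction_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  all <- do.call(rbind, lapply(sets, validate_junctions))
  key <- paste(all$chrom, all$start, all$end, all$strand, sep = ":")
  cnt <- rowsum(all$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  out$count <- as.integer(cnt[match(key[first], rownames(cnt)), 1])
  out <- out[order(out$chrom, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Binomially thin junction read counts
#'
#' Emulates a shallower sequencing run: each junction's count is replaced by
#' a Binomial(count, keep_fraction) draw, and junctions whose thinned count
#' is zero are removed.
#'
#' @param junctions Junction data.frame.
#' @param keep_fraction Probability in \[0, 1\] of keeping each read.
#' @param seed Optional integer seed for reproducibility.
#' @return Thinned junction data.frame.
#' @export
thin_counts <- function(junctions, keep_fraction, seed = NULL) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  j <- validate_junctions(junctions)
  if (!is.null(seed)) set.seed(seed)
  j$count <- stats::rbinom(nrow(j), j$count, keep_fraction)
  j <- j[j$count > 0, , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Cluster junctions into alternative-excision intron clusters
#'
#' Junctions longer than `max_intron_len` are removed first. Remaining
#' junctions (same chrom, and same strand when `strand_aware`) are linked
#' when they share a start (donor) or an end (acceptor) coordinate; clusters
#' are the connected components of that graph. Single-junction components are
#' discarded (a lone junction evidences no alternative excision), as are
#' clusters whose total read support is below `min_cluster_reads`.
#'
#' @param junctions Junction data.frame.
#' @param max_intron_len Maximum intron length in bp (default 500000).
#' @param min_cluster_reads Minimum total reads per cluster (default 30).
#' @param strand_aware If TRUE (default) junctions only cluster within a
#'   strand ("." is its own stratum); if FALSE strand is ignored.
#' @param min_junction_fraction Optional within-cluster usage pruning: while
#'   any junction carries less than this fraction of its cluster's reads, the
#'   lowest-usage junction is removed and the cluster re-checked. Default 0
#'   (no pruning).
#' @return An `intron_clusters` object: list with `clusters` (cluster_id,
#'   chrom, strand, gene_id, m, total_reads) and `junctions` (input rows that
#'   survived, with a cluster_id column).
#' @export
cluster_junctions <- function(junctions, max_intron_len = 500000,
                              min_cluster_reads = 30, strand_aware = TRUE,
                              min_junction_fraction = 0) {
  j <- validate_junctions(junctions)
  j <- j[(j$end - j$start) <= max_intron_len, , drop = FALSE]
  ## canonical order makes clustering order-invariant
  j <- j[order(j$chrom, j$start, j$end, j$strand), , drop = FALSE]
  rownames(j) <- NULL
  if (!nrow(j)) return(.empty_clusters(j))

  strand_key <- if (strand_aware) j$strand else "*"
  start_key <- paste(j$chrom, strand_key, "s", j$start)
  end_key <- paste(j$chrom, strand_key, "e", j$end)
  edges <- rbind(.group_edges(start_key), .group_edges(end_key))
  g <- igraph::make_empty_graph(n = nrow(j), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  keep <- logical(nrow(j))
  members <- split(seq_len(nrow(j)), comp)
  for (idx in members) {
    if (length(idx) < 2L) next
    if (min_junction_fraction > 0) {
      repeat {
        tot <- sum(j$count[idx])
        frac <- j$count[idx] / tot
        if (length(idx) < 2L || all(frac >= min_junction_fraction)) break
        idx <- idx[-which.min(frac)]
      }
      if (length(idx) < 2L) next
    }
    if (sum(j$count[idx]) < min_cluster_reads) next
    keep[idx] <- TRUE
  }
  jk <- j[keep, , drop = FALSE]
  ck <- comp[keep]
  if (!nrow(jk)) return(.empty_clusters(jk))
  ## deterministic ids in genomic order of the first member
  first <- !duplicated(ck)
  ord <- order(jk$chrom[first], jk$start[first], jk$end[first])
  relabel <- stats::setNames(order(ord), ck[first])
  jk$cluster_id <- sprintf("clu_%d", relabel[as.character(ck)])
  jk <- jk[order(as.integer(sub("clu_", "", jk$cluster_id)),
                 jk$start, jk$end), ]
  rownames(jk) <- NULL
  ids <- unique(jk$cluster_id)
  strand_of <- vapply(split(jk$strand, jk$cluster_id)[ids], function(s)
    if (length(unique(s)) == 1L) s[1] else ".", character(1))
  clusters <- data.frame(
    cluster_id = ids,
    chrom = jk$chrom[match(ids, jk$cluster_id)],
    strand = unname(strand_of),
    gene_id = NA_character_,
    m = as.integer(table(jk$cluster_id)[ids]),
    total_reads = as.integer(rowsum(jk$count, jk$cluster_id)[ids, 1]),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, junctions = jk),
            class = "intron_clusters")
}

.group_edges <- function(key) {
  o <- order(key)
  same <- key[o][-1] == key[o][-length(o)]
  cbind(o[-length(o)][same], o[-1][same])
}

.empty_clusters <- function(j) {
  j$cluster_id <- character(0)
  structure(list(
    clusters = data.frame(cluster_id = character(0), chrom = character(0),
                          strand = character(0), gene_id = character(0),
                          m = integer(0), total_reads = integer(0),
                          stringsAsFactors = FALSE),
    junctions = j), class = "intron_clusters")
}

#' @export
print.intron_clusters <- function(x, ...) {
  cat("intron_clusters:", nrow(x$clusters), "clusters over",
      nrow(x$junctions), "junctions;",
      sum(!is.na(x$clusters$gene_id)), "gene-assigned\n")
  invisible(x)
}

#' Assign intron clusters to genes and drop ambiguous clusters
#'
#' A cluster is assigned to a gene when every junction interval lies within
#' that gene's span (junction coordinates are intronic, so gene span rather
#' than exon overlap is used). Clusters whose junctions touch the spans of
#' two or more genes connect multiple reference genes and are dropped, as are
#' clusters touching no gene.
#'
#' @param clusters An `intron_clusters` object.
#' @param annotation A `genome_annotation`.
#' @param strand_aware If TRUE (default) a stranded junction only matches
#'   genes on its strand; "." junctions match either strand.
#' @return An `intron_clusters` object restricted to gene-assigned clusters,
#'   with `gene_id` filled in.
#' @export
assign_and_filter_clusters <- function(clusters, annotation,
                                       strand_aware = TRUE) {
  stopifnot(inherits(clusters, "intron_clusters"),
            inherits(annotation, "genome_annotation"))
  j <- clusters$junctions
  if (!nrow(j)) return(clusters)
  g <- annotation$genes
  jg <- GenomicRanges::GRanges(j$chrom,
                               IRanges::IRanges(j$start + 1L, j$end))
  gg <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  touch <- GenomicRanges::findOverlaps(jg, gg, type = "any",
                                       ignore.strand = TRUE)
  within <- GenomicRanges::findOverlaps(jg, gg, type = "within",
                                        ignore.strand = TRUE)
  ok_strand <- function(h) {
    if (!strand_aware) return(rep(TRUE, length(h)))
    js <- j$strand[S4Vectors::queryHits(h)]
    gs <- g$strand[S4Vectors::subjectHits(h)]
    js == "." | js == gs
  }
  touch <- touch[ok_strand(touch)]
  within <- within[ok_strand(within)]

  cid <- j$cluster_id
  ## distinct (cluster, gene) touch pairs; clusters touching >1 gene are out
  tp <- unique(data.frame(
    cid = cid[S4Vectors::queryHits(touch)],
    gene = g$gene_id[S4Vectors::subjectHits(touch)],
    stringsAsFactors = FALSE))
  n_touched <- table(tp$cid)
  tp1 <- tp[tp$cid %in% names(n_touched)[n_touched == 1L], , drop = FALSE]

  ## candidate accepted iff all m junctions lie within the single gene's span
  n_within <- table(paste(cid[S4Vectors::queryHits(within)],
                          g$gene_id[S4Vectors::subjectHits(within)]))
  cl <- clusters$clusters
  m_of <- stats::setNames(cl$m, cl$cluster_id)
  k <- n_within[paste(tp1$cid, tp1$gene)]
  tp1 <- tp1[!is.na(k) & k == m_of[tp1$cid], , drop = FALSE]

  cl$gene_id <- tp1$gene[match(cl$cluster_id, tp1$cid)]
  keep <- !is.na(cl$gene_id)
  cl <- cl[keep, , drop = FALSE]
  rownames(cl) <- NULL
  jk <- j[j$cluster_id %in% cl$cluster_id, , drop = FALSE]
  rownames(jk) <- NULL
  structure(list(clusters = cl, junctions = jk), class = "intron_clusters")
}

#' Export clusters as a flat table
#'
#' @param clusters An `intron_clusters` object.
#' @return data.frame with one row per cluster: cluster_id, chrom, strand,
#'   gene_id, m, total_reads and a comma-separated junction list.
#' @export
cluster_table <- function(clusters) {
  cl <- clusters$clusters
  j <- clusters$junctions
  jl <- vapply(cl$cluster_id, function(id) {
    d <- j[j$cluster_id == id, ]
    paste(sprintf("%d-%d:%d", d$start, d$end, d$count), collapse = ",")
  }, character(1))
  cl$junctions <- unname(jl)
  cl
}
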