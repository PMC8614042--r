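#' Read a gene annotation into a `genome_annotation` object
#'
#' Parses a GTF2 or GFF3 file into the package's internal gene-model tables.
#' Source coordinates (1-based, inclusive) are converted to 0-based half-open
#' intervals on read, so interval arithmetic downstream is unambiguous.
#'
#' GTF features are attached via their `gene_id`/`transcript_id` attributes;
#' GFF3 features via `ID`/`Parent` chains (exon/CDS -> mRNA/transcript ->
#' gene). Transcripts with no exon features are dropped with a warning.
#'
#' @param path Path to the annotation file.
#' @param format `"GTF2"` or `"GFF3"`. Defaults to guessing from the file
#'   extension (`.gtf` vs `.gff`/`.gff3`).
#' @return A `genome_annotation` object: a list with data frames `genes`
#'   (gene_id, chrom, strand, start, end), `transcripts` (transcript_id,
#'   gene_id) and `exons`/`cds` (transcript_id, gene_id, chrom, strand,
#'   start, end), all 0-based half-open, plus the `source_format`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "GTF2", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gtf") "GTF2" else "GFF3"
  }
  gr <- rtracklayer::import(path,
                            format = if (format == "GTF2") "gtf" else "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  ## convert 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  if (format == "GTF2") {
    ann <- .annotation_from_gtf_table(df)
  } else {
    ann <- .annotation_from_gff3_table(df)
  }
  ann$source_format <- format
  ann
}

.annotation_from_gtf_table <- function(df) {
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L) stop("annotation contains no exon features")
  if (is.null(ex$gene_id) || is.null(ex$transcript_id))
    stop("GTF exon features must carry gene_id and transcript_id attributes")
  .build_annotation(
    exons = data.frame(transcript_id = ex$transcript_id, gene_id = ex$gene_id,
                       chrom = ex$seqnames, strand = ex$strand,
                       start = ex$start0, end = ex$end0,
                       stringsAsFactors = FALSE),
    cds = if (nrow(cds))
      data.frame(transcript_id = cds$transcript_id, gene_id = cds$gene_id,
                 chrom = cds$seqnames, strand = cds$strand,
                 start = cds$start0, end = cds$end0,
                 stringsAsFactors = FALSE)
    else NULL)
}

.annotation_from_gff3_table <- function(df) {
  ## Parent is a CharacterList after import; flatten (features here have one)
  parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  id <- as.character(df$ID)
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_parent <- parent[df$type %in% c("mRNA", "transcript")]
  tx_id <- id[df$type %in% c("mRNA", "transcript")]
  if (nrow(tx) == 0L) stop("GFF3 annotation contains no mRNA/transcript features")
  gene_of_tx <- stats::setNames(tx_parent, tx_id)

  take <- function(type) {
    keep <- df$type == type
    sub <- df[keep, , drop = FALSE]
    par <- parent[keep]
    known <- par %in% names(gene_of_tx)
    if (any(!known))
      warning(sum(!known), " ", type,
              " feature(s) with unknown Parent dropped")
    sub <- sub[known, , drop = FALSE]
    par <- par[known]
    if (!nrow(sub)) return(NULL)
    data.frame(transcript_id = par, gene_id = unname(gene_of_tx[par]),
               chrom = sub$seqnames, strand = sub$strand,
               start = sub$start0, end = sub$end0, stringsAsFactors = FALSE)
  }
  .build_annotation(exons = take("exon"), cds = take("CDS"))
}

## Assemble/validate the internal tables; shared by readers and the simulator.
.build_annotation <- function(exons, cds = NULL) {
  if (is.null(exons) || !nrow(exons)) stop("no exon records")
  stopifnot(all(exons$start >= 0), all(exons$end > exons$start))
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL

  tx_all <- unique(exons[, c("transcript_id", "gene_id")])
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$gene_id, cds$transcript_id, cds$start), ]
    rownames(cds) <- NULL
    orphans <- setdiff(cds$transcript_id, tx_all$transcript_id)
    if (length(orphans)) {
      warning(length(orphans), " transcript(s) with CDS but no exons dropped")
      cds <- cds[!cds$transcript_id %in% orphans, , drop = FALSE]
    }
  } else {
    cds <- exons[0, , drop = FALSE]
  }

  gids <- sort(unique(exons$gene_id))
  first <- match(gids, exons$gene_id)
  genes <- data.frame(
    gene_id = gids, chrom = exons$chrom[first], strand = exons$strand[first],
    start = as.integer(vapply(split(exons$start, exons$gene_id), min,
                              numeric(1))[gids]),
    end = as.integer(vapply(split(exons$end, exons$gene_id), max,
                            numeric(1))[gids]),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")

  structure(list(genes = genes, transcripts = tx_all, exons = exons,
                 cds = cds, source_format = NA_character_),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS segments",
      sprintf("(source %s)\n", x$source_format))
  invisible(x)
}

#' Extract a single gene model
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @return A `gene_model` list: gene_id, chrom, strand, span (0-based
#'   half-open c(start, end)) and a named list of transcripts, each with
#'   `exons` and `cds` two-column matrices (start, end).
#' @export
gene_model <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene_id: ", gene_id)
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  cd <- annotation$cds[annotation$cds$gene_id == gene_id, , drop = FALSE]
  tids <- sort(unique(ex$transcript_id))
  transcripts <- lapply(tids, function(t) {
    e <- ex[ex$transcript_id == t, , drop = FALSE]
    k <- cd[cd$transcript_id == t, , drop = FALSE]
    list(exons = cbind(start = e$start, end = e$end),
         cds = cbind(start = k$start, end = k$end))
  })
  names(transcripts) <- tids
  structure(list(gene_id = gene_id, chrom = g$chrom, strand = g$strand,
                 span = c(g$start, g$end), transcripts = transcripts),
            class = "gene_model")
}

## representative transcript id per gene: longest summed exon length,
## ties broken by transcript_id for determinism
.representative_tx <- function(annotation) {
  ex <- annotation$exons
  len <- rowsum(ex$end - ex$start, ex$transcript_id)
  tx <- annotation$transcripts
  tx$len <- len[match(tx$transcript_id, rownames(len)), 1]
  tx <- tx[order(tx$gene_id, -tx$len, tx$transcript_id), ]
  tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id", "len")]
}

#' Derive intron intervals for a gene
#'
#' Introns are the gaps between consecutive exons of the chosen representative
#' structure: either the longest isoform (transcript with greatest summed exon
#' length) or the union of all exon intervals across isoforms.
#'
#' @param gene A `gene_model`.
#' @param representative `"longest_isoform"` (default) or `"union"`.
#' @return Two-column matrix (start, end) of intron intervals, 0-based
#'   half-open; zero rows for single-exon genes.
#' @export
derive_introns <- function(gene,
                           representative = c("longest_isoform", "union")) {
  representative <- match.arg(representative)
  stopifnot(inherits(gene, "gene_model"), length(gene$transcripts) >= 1)
  if (representative == "longest_isoform") {
    lens <- vapply(gene$transcripts,
                   function(t) sum(t$exons[, "end"] - t$exons[, "start"]),
                   numeric(1))
    best <- sort(names(gene$transcripts)[lens == max(lens)])[1]
    ex <- gene$transcripts[[best]]$exons
  } else {
    all_ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
    ex <- .reduce_intervals(all_ex)
  }
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  if (nrow(ex) < 2L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ex[-nrow(ex), "end"], end = ex[-1, "start"])
}

## merge overlapping/adjacent intervals; m is a (start,end) matrix
.reduce_intervals <- function(m) {
  m <- m[order(m[, "start"], m[, "end"]), , drop = FALSE]
  if (nrow(m) <= 1L) return(m)
  out <- list(m[1, ])
  for (i in 2:nrow(m)) {
    cur <- out[[length(out)]]
    if (m[i, "start"] <= cur["end"]) {
      cur["end"] <- max(cur["end"], m[i, "end"])
      out[[length(out)]] <- cur
    } else out[[length(out) + 1L]] <- m[i, ]
  }
  do.call(rbind, out)
}

#' Per-gene intron-size statistics
#'
#' Computes the three intron-size-related statistics for one gene:
#' mean intron size, CDS density (mean summed CDS length across transcripts
#' divided by gene span length) and intron density (introns per kb of exon,
#' on the representative transcript).
#'
#' @param gene A `gene_model`.
#' @param representative Passed to [derive_introns()].
#' @return An `intron_stats` list: mean_intron_size (NA for single-exon
#'   genes), cds_density (NA for genes without CDS), intron_density,
#'   n_introns, n_genes (= 1).
#' @export
gene_intron_stats <- function(gene,
                              representative = c("longest_isoform", "union")) {
  representative <- match.arg(representative)
  introns <- derive_introns(gene, representative)
  lens <- vapply(gene$transcripts,
                 function(t) sum(t$exons[, "end"] - t$exons[, "start"]),
                 numeric(1))
  best <- sort(names(gene$transcripts)[lens == max(lens)])[1]
  exon_len <- if (representative == "union") {
    u <- .reduce_intervals(do.call(rbind, lapply(gene$transcripts, `[[`, "exons")))
    sum(u[, "end"] - u[, "start"])
  } else lens[[best]]
  if (exon_len <= 0) stop("gene ", gene$gene_id, " has zero exon length")
  span_len <- gene$span[2] - gene$span[1]
  cds_tot <- vapply(gene$transcripts,
                    function(t) sum(t$cds[, "end"] - t$cds[, "start"]),
                    numeric(1))
  has_cds <- any(cds_tot > 0)
  n_introns <- nrow(introns)
  structure(list(
    mean_intron_size = if (n_introns) mean(introns[, "end"] - introns[, "start"]) else NA_real_,
    cds_density = if (has_cds) mean(cds_tot) / span_len else NA_real_,
    intron_density = n_introns / (exon_len / 1000),
    n_introns = n_introns,
    n_genes = 1L), class = "intron_stats")
}

#' Vectorised per-gene intron/exon/CDS table
#'
#' One row per gene over the whole annotation: representative transcript,
#' exon/intron/CDS lengths and the three intron-size statistics. This is the
#' workhorse behind [genome_intron_stats()] and the within-genome
#' ASL-versus-intron-size analysis.
#'
#' @param annotation A `genome_annotation`.
#' @return data.frame with gene_id, transcript_id (representative), n_exons,
#'   n_introns, exon_len, intron_len, span_len, mean_intron_size,
#'   cds_density, intron_density, is_multi_exon.
#' @export
gene_intron_table <- function(annotation) {
  rep_tx <- .representative_tx(annotation)
  ex <- annotation$exons
  ex <- ex[ex$transcript_id %in% rep_tx$transcript_id, , drop = FALSE]
  ex <- ex[order(ex$transcript_id, ex$start), ]
  n_ex <- c(table(ex$transcript_id))
  exon_len <- rowsum(ex$end - ex$start, ex$transcript_id)[, 1]

  ## intron gaps within each representative transcript (exons sorted)
  same_tx <- ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)]
  gap_start <- ex$end[-nrow(ex)][same_tx]
  gap_end <- ex$start[-1][same_tx]
  gap_tx <- ex$transcript_id[-nrow(ex)][same_tx]
  intron_len <- rowsum(gap_end - gap_start, gap_tx)[, 1]
  n_intr <- c(table(gap_tx))

  tx <- rep_tx$transcript_id
  out <- data.frame(
    gene_id = rep_tx$gene_id,
    transcript_id = tx,
    n_exons = as.integer(n_ex[tx]),
    n_introns = ifelse(is.na(n_intr[tx]), 0L, as.integer(n_intr[tx])),
    exon_len = as.numeric(exon_len[tx]),
    intron_len = ifelse(is.na(intron_len[tx]), 0, as.numeric(intron_len[tx])),
    stringsAsFactors = FALSE)
  g <- annotation$genes
  out$span_len <- (g$end - g$start)[match(out$gene_id, g$gene_id)]
  out$mean_intron_size <- ifelse(out$n_introns > 0,
                                 out$intron_len / out$n_introns, NA_real_)

  ## mean summed CDS length across all transcripts of the gene
  cd <- annotation$cds
  if (nrow(cd)) {
    cds_by_tx <- rowsum(cd$end - cd$start, cd$transcript_id)[, 1]
    all_tx <- annotation$transcripts
    all_tx$cds_len <- ifelse(is.na(cds_by_tx[all_tx$transcript_id]), 0,
                             cds_by_tx[all_tx$transcript_id])
    mean_cds <- rowsum(all_tx$cds_len, all_tx$gene_id)[, 1] /
      c(table(all_tx$gene_id))[sort(unique(all_tx$gene_id))]
    has_cds <- rowsum(as.numeric(all_tx$cds_len > 0), all_tx$gene_id)[, 1] > 0
    out$cds_density <- ifelse(has_cds[out$gene_id],
                              mean_cds[out$gene_id] / out$span_len, NA_real_)
  } else {
    out$cds_density <- NA_real_
  }
  out$intron_density <- out$n_introns / (out$exon_len / 1000)
  out$is_multi_exon <- out$n_exons >= 2L
  rownames(out) <- NULL
  out
}

#' Genome-level intron-size statistics
#'
#' Aggregates [gene_intron_table()] to species level. `per_intron` (default)
#' averages intron sizes over all introns of multi-exon genes;
#' `per_gene_mean` averages the per-gene mean intron sizes. CDS density is
#' averaged over coding genes; intron density is total introns per total kb
#' of (representative) exon under `per_intron`, or the mean of per-gene
#' densities under `per_gene_mean`.
#'
#' @param annotation A `genome_annotation` (or a precomputed
#'   [gene_intron_table()] data.frame).
#' @param aggregation `"per_intron"` or `"per_gene_mean"`.
#' @return An `intron_stats` list; `mean_intron_size` is NA (with attribute
#'   `undefined = TRUE`) when no multi-exon gene exists.
#' @export
genome_intron_stats <- function(annotation,
                                aggregation = c("per_intron", "per_gene_mean")) {
  aggregation <- match.arg(aggregation)
  tab <- if (is.data.frame(annotation)) annotation else gene_intron_table(annotation)
  multi <- tab[tab$is_multi_exon, , drop = FALSE]
  undefined <- nrow(multi) == 0L
  if (undefined) warning("no multi-exon genes: mean intron size undefined")
  mis <- if (undefined) NA_real_ else if (aggregation == "per_intron")
    sum(multi$intron_len) / sum(multi$n_introns)
  else mean(multi$mean_intron_size)
  idens <- if (aggregation == "per_intron")
    sum(tab$n_introns) / (sum(tab$exon_len) / 1000)
  else mean(tab$intron_density)
  res <- structure(list(
    mean_intron_size = mis,
    cds_density = if (all(is.na(tab$cds_density))) NA_real_
                  else mean(tab$cds_density, na.rm = TRUE),
    intron_density = idens,
    n_introns = sum(tab$n_introns),
    n_genes = nrow(tab)), class = "intron_stats")
  attr(res, "undefined") <- undefined
  res
}

#' @export
print.intron_stats <- function(x, ...) {
  cat(sprintf(paste0("intron stats: mean intron size %.1f bp, CDS density ",
                     "%.3f, intron density %.3f /kb exon (%d introns, %d genes)\n"),
              x$mean_intron_size, x$cds_density, x$intron_density,
              x$n_introns, x$n_genes))
  invisible(x)
}

#' Write an annotation as GTF2
#'
#' Emits gene/transcript/exon/CDS features with `gene_id`/`transcript_id`
#' attributes, converting internal 0-based half-open coordinates back to the
#' 1-based inclusive file convention.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  lines <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tspliceprev\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  g <- annotation$genes
  lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                        sprintf("gene_id \"%s\";", g$gene_id)))
  tx <- annotation$transcripts
  ex <- annotation$exons
  tx_first <- ex[!duplicated(ex$transcript_id), ]
  tx_span_s <- rowsum(ex$start, ex$transcript_id, reorder = FALSE)
  tx_lo <- vapply(split(ex$start, ex$transcript_id), min, numeric(1))
  tx_hi <- vapply(split(ex$end, ex$transcript_id), max, numeric(1))
  tids <- names(tx_lo)
  gid <- tx$gene_id[match(tids, tx$transcript_id)]
  chrom <- ex$chrom[match(tids, ex$transcript_id)]
  strand <- ex$strand[match(tids, ex$transcript_id)]
  lines <- c(lines, fmt(chrom, "transcript", as.integer(tx_lo),
                        as.integer(tx_hi), strand,
                        sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                                gid, tids)))
  attr_of <- function(d) sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                                 d$gene_id, d$transcript_id)
  lines <- c(lines, fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
                        attr_of(ex)))
  cd <- annotation$cds
  if (nrow(cd))
    lines <- c(lines, fmt(cd$chrom, "CDS", cd$start, cd$end, cd$strand,
                          attr_of(cd)))
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' @inheritParams write_gtf
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tspliceprev\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  lines <- "##gff-version 3"
  g <- annotation$genes
  lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                        sprintf("ID=%s", g$gene_id)))
  ex <- annotation$exons
  tx <- annotation$transcripts
  tx_lo <- vapply(split(ex$start, ex$transcript_id), min, numeric(1))
  tx_hi <- vapply(split(ex$end, ex$transcript_id), max, numeric(1))
  tids <- names(tx_lo)
  gid <- tx$gene_id[match(tids, tx$transcript_id)]
  chrom <- ex$chrom[match(tids, ex$transcript_id)]
  strand <- ex$strand[match(tids, ex$transcript_id)]
  lines <- c(lines, fmt(chrom, "mRNA", as.integer(tx_lo), as.integer(tx_hi),
                        strand, sprintf("ID=%s;Parent=%s", tids, gid)))
  lines <- c(lines, fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
                        sprintf("ID=exon-%s-%d;Parent=%s", ex$transcript_id,
                                seq_len(nrow(ex)), ex$transcript_id)))
  cd <- annotation$cds
  if (nrow(cd))
    lines <- c(lines, fmt(cd$chrom, "CDS", cd$start, cd$end, cd$strand,
                          sprintf("ID=cds-%s-%d;Parent=%s", cd$transcript_id,
                                  seq_len(nrow(cd)), cd$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
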