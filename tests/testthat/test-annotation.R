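test_that("GTF and GFF3 round-trips preserve intervals and structure", {
  ann <- demo_annotation()
  for (writer in list(write_gtf, write_gff3)) {
    path <- tempfile(fileext = if (identical(writer, write_gtf)) ".gtf"
                     else ".gff3")
    writer(ann, path)
    back <- read_gene_annotation(path)
    expect_equal(back$exons[, c("transcript_id", "gene_id", "chrom",
                                "strand", "start", "end")],
                 ann$exons[, c("transcript_id", "gene_id", "chrom",
                               "strand", "start", "end")])
    expect_equal(back$cds[, c("transcript_id", "start", "end")],
                 ann$cds[, c("transcript_id", "start", "end")])
    expect_equal(back$genes, ann$genes)
  }
})

test_that("1-based inclusive source coordinates become 0-based half-open", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    path)
  ann <- read_gene_annotation(path, format = "GTF2")
  expect_equal(ann$exons$start, c(100, 300))
  expect_equal(ann$exons$end, c(200, 400))
})

test_that("multi-transcript genes are retained and GFF3 CDS attach to the right transcript", {
  ann <- demo_annotation()
  gm <- gene_model(ann, "geneA")
  expect_length(gm$transcripts, 2)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gene_annotation(path, format = "GFF3")
  cds_a2 <- back$cds[back$cds$transcript_id == "tA2", ]
  expect_equal(cds_a2$start, c(120, 600))
  expect_equal(cds_a2$end, c(200, 650))
})

test_that("derive_introns returns exon gaps of the chosen representative", {
  ex <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c",
                   strand = "+", start = c(0, 200, 500),
                   end = c(100, 300, 600))
  ann <- spliceprev:::.build_annotation(ex)
  intr <- derive_introns(gene_model(ann, "g1"))
  expect_equal(unname(intr[, "start"]), c(100, 300))
  expect_equal(unname(intr[, "end"]), c(200, 500))
  expect_equal(unname(intr[, "end"] - intr[, "start"]), c(100, 200))

  # single-exon gene: no introns
  single <- spliceprev:::.build_annotation(
    data.frame(transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
               start = 0, end = 500))
  expect_equal(nrow(derive_introns(gene_model(single, "g"))), 0)

  # longest isoform wins: tA1 (300 bp exon total) over tA2 (200 bp)
  gm <- gene_model(demo_annotation(), "geneA")
  intr <- derive_introns(gm, "longest_isoform")
  expect_equal(nrow(intr), 2)          # tA1's two gaps
  expect_equal(unname(intr[1, ]), c(200, 300))
  # union collapses to the same exons here
  expect_equal(nrow(derive_introns(gm, "union")), 2)
})

test_that("gene_intron_stats computes the three statistics", {
  # introns of 100 and 200 bp
  ex <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c",
                   strand = "+", start = c(0, 200, 500),
                   end = c(100, 300, 600))
  st <- gene_intron_stats(gene_model(spliceprev:::.build_annotation(ex), "g1"))
  expect_equal(st$mean_intron_size, 150)

  # gene span 1000, transcript CDS totals 600 and 300 -> density 0.45
  ex2 <- rbind(
    data.frame(transcript_id = "ta", gene_id = "g", chrom = "c", strand = "+",
               start = c(0, 900), end = c(600, 1000)),
    data.frame(transcript_id = "tb", gene_id = "g", chrom = "c", strand = "+",
               start = 0, end = 300))
  cds2 <- rbind(
    data.frame(transcript_id = "ta", gene_id = "g", chrom = "c", strand = "+",
               start = 0, end = 600),
    data.frame(transcript_id = "tb", gene_id = "g", chrom = "c", strand = "+",
               start = 0, end = 300))
  st2 <- gene_intron_stats(
    gene_model(spliceprev:::.build_annotation(ex2, cds2), "g"))
  expect_equal(st2$cds_density, 0.45)

  # 3 introns over 1500 bp of exon -> 2 per kb
  ex3 <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                    strand = "+", start = c(0, 500, 1000, 1500),
                    end = c(375, 875, 1375, 1875))
  st3 <- gene_intron_stats(gene_model(spliceprev:::.build_annotation(ex3), "g"))
  expect_equal(st3$n_introns, 3)
  expect_equal(st3$intron_density, 2)
})

test_that("genome_intron_stats honours the aggregation rule", {
  # gene 1: one intron of 100; gene 2: three introns of 300 each
  ex <- rbind(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c", strand = "+",
               start = c(0, 200), end = c(100, 300)),
    data.frame(transcript_id = "t2", gene_id = "g2", chrom = "c", strand = "+",
               start = c(1000, 1400, 1800, 2200),
               end = c(1100, 1500, 1900, 2300)))
  ann <- spliceprev:::.build_annotation(ex)
  expect_equal(genome_intron_stats(ann, "per_gene_mean")$mean_intron_size, 200)
  expect_equal(genome_intron_stats(ann, "per_intron")$mean_intron_size, 250)

  only_single <- spliceprev:::.build_annotation(
    data.frame(transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
               start = 0, end = 100))
  expect_warning(st <- genome_intron_stats(only_single), "undefined")
  expect_true(is.na(st$mean_intron_size))
  expect_true(attr(st, "undefined"))
})

test_that("exon plus intron lengths reconstruct the transcript span, and intron density is translation-invariant", {
  ann <- simulate_gene_catalog(150, seed = 9, frac_alt = 0.5)
  tab <- gene_intron_table(ann)
  g <- ann$genes
  span <- (g$end - g$start)[match(tab$gene_id, g$gene_id)]
  expect_equal(tab$exon_len + tab$intron_len, span)

  shifted <- ann
  shifted$exons$start <- shifted$exons$start + 10000L
  shifted$exons$end <- shifted$exons$end + 10000L
  shifted$cds$start <- shifted$cds$start + 10000L
  shifted$cds$end <- shifted$cds$end + 10000L
  shifted$genes$start <- shifted$genes$start + 10000L
  shifted$genes$end <- shifted$genes$end + 10000L
  expect_equal(genome_intron_stats(shifted)$intron_density,
               genome_intron_stats(ann)$intron_density)
})
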