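test_that("cluster entropy matches the Shannon formula and its boundary cases", {
  expect_equal(cluster_entropy(c(5, 5)), 1)
  expect_equal(cluster_entropy(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(cluster_entropy(7), 0)
  expect_error(cluster_entropy(c(0, 0)), "all-zero")
  expect_error(cluster_entropy(numeric(0)), "empty")
  expect_error(cluster_entropy(c(3, -1)), "negative")
})

test_that("entropy is permutation- and scale-invariant and merging uniform junctions loses one bit", {
  set.seed(8)
  for (i in 1:25) {
    counts <- rpois(sample(2:8, 1), 20) + 1
    expect_equal(cluster_entropy(sample(counts)), cluster_entropy(counts))
    expect_equal(cluster_entropy(counts * 7), cluster_entropy(counts))
    expect_lte(cluster_entropy(counts), log2(length(counts)) + 1e-12)
  }
  # two equal junctions merged into one: H drops from 1 bit to 0
  expect_equal(cluster_entropy(c(10, 10)) - cluster_entropy(20), 1)
})

test_that("gene-level ASL sums cluster entropies", {
  expect_equal(gene_asl_junction(list(cluster_entropies = c(1, 0.5))), 1.5)
  expect_equal(gene_asl_junction(list(cluster_entropies = numeric(0))), 0)
  expect_equal(gene_asl_junction(list(cluster_entropies = rep(1, 3))), 3)
})

test_that("expression proxy is the max exonic depth, ignoring introns", {
  ann <- demo_annotation()
  gm <- gene_model(ann, "geneA")  # exons [100,200) [300,400) [600,700)
  cov <- data.frame(chrom = "chr1",
                    start = c(100, 150, 220, 300, 600),
                    end = c(150, 200, 280, 400, 700),
                    depth = c(5, 17, 30, 9, 2))
  expect_equal(approximate_expression(cov, gm), 17)  # intronic 30 ignored

  none <- data.frame(chrom = "chr9", start = 0, end = 10, depth = 5)
  expect_warning(e <- approximate_expression(none, gm), "absent")
  expect_equal(e, 0)
})

test_that("the expressed multi-exon rule is strict in depth and exon count", {
  ann <- demo_annotation()
  gm <- gene_model(ann, "geneA")
  flat2 <- data.frame(chrom = "chr1", start = 100, end = 700, depth = 2)
  expect_false(expressed_multiexon_flag(gm, flat2))
  one3 <- rbind(flat2, data.frame(chrom = "chr1", start = 150, end = 151,
                                  depth = 3))
  expect_true(expressed_multiexon_flag(gm, one3))

  gb <- gene_model(ann, "geneB")  # single exon
  deep <- data.frame(chrom = "chr1", start = 2000, end = 2500, depth = 100)
  expect_false(expressed_multiexon_flag(gb, deep))
})

test_that("species ASP follows each counting mode's numerator rule", {
  r <- rec_table(expression = c(10, 10, 10, 10), is_multi_exon = TRUE,
                 n_clusters = c(1L, 2L, 1L, 0L))
  expect_equal(species_asp(r, "junction"), 0.75)

  ri <- rec_table(expression = 5, is_multi_exon = TRUE,
                  n_isoforms = c(1L, 1L, 2L))
  expect_equal(species_asp(ri, "isoform"), 1 / 3)

  # an event with only 4 supporting reads does not count
  expect_equal(n_supported_events(c(4)), 0L)
  expect_equal(n_supported_events(c(5, 4, 12)), 2L)
  re <- rec_table(expression = 5, is_multi_exon = TRUE,
                  n_events = c(n_supported_events(4), 2L))
  expect_equal(species_asp(re, "event"), 0.5)

  # FPKM rule is strict
  rf <- rec_table(expression = c(0.1, 0.2), is_multi_exon = TRUE,
                  n_isoforms = 2L)
  expect_equal(species_asp(rf, "isoform"), 1)  # only the 0.2 gene counts
  expect_error(species_asp(rf[1, ], "isoform"), "no expressed")
})

test_that("species ASL averages the mode's per-gene quantity", {
  ri <- rec_table(expression = 5, is_multi_exon = TRUE,
                  n_isoforms = c(1L, 2L, 3L))
  expect_equal(species_asl(ri, "isoform"), 2)

  rj <- rec_table(expression = 10, is_multi_exon = TRUE,
                  entropy_asl = c(0, 1, 0.5))
  expect_equal(species_asl(rj, "junction"), 0.5)

  re <- rec_table(expression = 5, is_multi_exon = TRUE, n_events = c(0L, 0L))
  expect_equal(species_asl(re, "event"), 0)
})

test_that("ASP responds monotonically to adding spliced or unspliced genes", {
  base <- rec_table(expression = 10, is_multi_exon = TRUE,
                    n_clusters = c(1L, 0L, 1L))
  asp0 <- species_asp(base, "junction")
  plus_spliced <- rbind(base, rec_table(expression = 10,
                                        is_multi_exon = TRUE,
                                        n_clusters = 1L))
  expect_gte(species_asp(plus_spliced, "junction"), asp0)
  plus_unspliced <- rbind(base, rec_table(expression = 10,
                                          is_multi_exon = TRUE,
                                          n_clusters = 0L))
  expect_lte(species_asp(plus_unspliced, "junction"), asp0)
})

test_that("with near-complete detection, junction-mode ASP matches the simulated truth", {
  cfg <- sim_config(n_species = 2, n_genes = 2000, read_rate = 50,
                    expr_meanlog = log(50), expr_sdlog = 0.8)
  b <- simulate_species_set(cfg, seed = 31)
  for (sp in names(b$species)) {
    s <- b$species[[sp]]
    cl <- assign_and_filter_clusters(cluster_junctions(s$junctions),
                                     s$annotation)
    rec <- gene_splicing_records(s$annotation, cl, coverage = s$coverage)
    est <- species_asp(rec, "junction")
    truth <- b$traits$true_asp[b$traits$species == sp]
    expect_lt(abs(est - truth), 0.02)
  }
})
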