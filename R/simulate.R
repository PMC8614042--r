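#' Simulation configuration
#'
#' Bundles the generative assumptions behind the cross-species splicing
#' analysis: a phylogeny, a cell-type-number-like complexity trait evolving
#' on it, per-gene exon/intron structure with lognormal intron sizes, a
#' species-level fraction of alternatively spliced genes coupled to
#' complexity, Beta-distributed junction usage within skipping events,
#' lognormal expression, and Poisson junction read counts proportional to
#' expression (which yields the depth-dependent detection the saturation
#' correction targets).
#'
#' @param n_species Number of species (tips).
#' @param tree_mode `"birth_death"` (simulated pure-birth tree) or
#'   `"provided"` (use `tree`).
#' @param tree A `phylo` tree when `tree_mode = "provided"`.
#' @param brownian_sigma Brownian SD per unit branch length of log cell type
#'   number (CTN).
#' @param lambda_true Pagel's lambda used when simulating the trait.
#' @param complexity_range CTN range; the exponentiated Brownian trait is
#'   clipped into it.
#' @param n_genes Genes per species.
#' @param single_exon_frac Fraction of genes with a single exon.
#' @param frac_alt_base Baseline fraction of multi-exon genes that are
#'   alternatively spliced.
#' @param complexity_slope Change in the alternatively spliced fraction from
#'   the bottom to the top of the complexity range (log scale), centred on
#'   `frac_alt_base`.
#' @param dirichlet_conc Concentration of the Beta(conc, conc) inclusion
#'   ratio of skipping events (the 2-isoform Dirichlet).
#' @param expr_meanlog,expr_sdlog Lognormal parameters of per-gene coverage
#'   depth.
#' @param read_rate Expected junction reads per unit coverage depth.
#' @param intron_meanlog,intron_sdlog Lognormal parameters of intron sizes
#'   (log-bp); the variance is split evenly between a gene-level and a
#'   within-gene component.
#' @param intron_species_sd Species-level SD added to `intron_meanlog`
#'   (log scale), giving species their own mean intron size.
#' @param intron_ctn_slope Coupling of the species intron-size location to
#'   scaled log complexity (log-bp across the complexity range; negative
#'   values emulate sets where larger genomes have lower complexity).
#' @param intron_coupling Within-genome coupling of a gene's alternative
#'   splicing probability to its standardised intron-size location.
#' @param mean_exons Mean exon count of multi-exon genes.
#' @param seed Default seed used when the generator is called without one.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 15, tree_mode = c("birth_death", "provided"),
                       tree = NULL, brownian_sigma = 0.6, lambda_true = 1,
                       complexity_range = c(20, 220), n_genes = 1500,
                       single_exon_frac = 0.2, frac_alt_base = 0.6,
                       complexity_slope = 0.7, dirichlet_conc = 2,
                       expr_meanlog = log(20), expr_sdlog = 1.2,
                       read_rate = 1, intron_meanlog = log(1500),
                       intron_sdlog = 1, intron_species_sd = 0.3,
                       intron_ctn_slope = 0, intron_coupling = 0,
                       mean_exons = 7, seed = 1) {
  tree_mode <- match.arg(tree_mode)
  stopifnot(n_species >= 2, n_genes >= 1,
            single_exon_frac >= 0, single_exon_frac < 1,
            frac_alt_base >= 0, frac_alt_base <= 1,
            dirichlet_conc > 0, read_rate > 0, brownian_sigma >= 0,
            lambda_true >= 0, lambda_true <= 1,
            complexity_range[1] <= complexity_range[2],
            complexity_range[1] > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d species, %d genes, CTN range [%g, %g],",
                     " alt fraction %.2f (slope %.2f), seed %d\n"),
              x$n_species, x$n_genes, x$complexity_range[1],
              x$complexity_range[2], x$frac_alt_base, x$complexity_slope,
              x$seed))
  invisible(x)
}

#' Simulate a continuous trait on a tree under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait vector over the tips with covariance
#' `sigma^2 * V(lambda)`, where V is the Brownian shared-path covariance and
#' Pagel's lambda scales its off-diagonal entries. The square root is taken
#' by eigendecomposition, so zero-distance tip pairs (perfectly correlated
#' under lambda = 1) are handled.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param sigma Brownian SD per unit branch length.
#' @param lambda_true Pagel's lambda in \[0, 1\].
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @param root Root (ancestral) trait value.
#' @return Named numeric vector over tip labels.
#' @export
simulate_traits_on_tree <- function(tree, sigma, lambda_true = 1,
                                    seed = NULL, root = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (sigma == 0) return(stats::setNames(rep(root, n), tree$tip.label))
  V <- sigma^2 * .lambda_vcv(ape::vcv(tree), lambda_true)
  eg <- eigen(V, symmetric = TRUE)
  half <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  y <- root + drop(half %*% stats::rnorm(n))
  stats::setNames(y, colnames(V))
}

#' Simulate a gene catalog (annotation) for one species
#'
#' Genes are laid out non-overlapping along synthetic chromosomes. A fixed
#' fraction of genes is single-exon (deterministic count via seeded rank
#' assignment); multi-exon genes get 2+Poisson exon counts, lognormal exon
#' widths and lognormal intron sizes whose gene-level location can be
#' coupled, through `intron_coupling`, to the gene's probability of being
#' alternatively spliced. Alternatively spliced genes (needing >= 3 exons)
#' carry a second transcript that skips one internal exon; CDS intervals
#' mirror the exons.
#'
#' @param n_genes Number of genes.
#' @param intron_meanlog,intron_sdlog Lognormal intron-size parameters.
#' @param single_exon_frac Fraction of single-exon genes (exact count).
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @param frac_alt Baseline probability that an eligible gene is
#'   alternatively spliced.
#' @param intron_coupling Added to the alt probability per SD of the gene's
#'   intron-size location.
#' @param mean_exons Mean exon count of multi-exon genes.
#' @param prefix Gene id prefix (also namespaces chromosomes).
#' @return A `genome_annotation` with a `truth` attribute: data.frame
#'   (gene_id, n_exons, is_multi_exon, alt, skip_exon, intron_mu, p_alt).
#' @export
simulate_gene_catalog <- function(n_genes, intron_meanlog = log(1500),
                                  intron_sdlog = 1, single_exon_frac = 0.2,
                                  seed = NULL, frac_alt = 0,
                                  intron_coupling = 0, mean_exons = 7,
                                  prefix = "g") {
  stopifnot(n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  gene_id <- sprintf("%s%05d", prefix, seq_len(n_genes))

  n_single <- round(single_exon_frac * n_genes)
  single <- rank(stats::runif(n_genes), ties.method = "first") <= n_single
  n_ex <- ifelse(single, 1L, 2L + stats::rpois(n_genes, max(mean_exons - 2, 0)))

  ## split lognormal variance between gene-level location and within-gene
  sd_part <- intron_sdlog / sqrt(2)
  intron_mu <- intron_meanlog + stats::rnorm(n_genes, 0, sd_part)
  z <- if (sd_part > 0) (intron_mu - intron_meanlog) / sd_part else rep(0, n_genes)

  eligible <- n_ex >= 3L
  p_alt <- pmin(pmax(frac_alt + intron_coupling * z, 0), 1)
  alt <- eligible & (stats::runif(n_genes) < p_alt)
  skip_exon <- ifelse(alt, 2L + floor(stats::runif(n_genes) *
                                        pmax(n_ex - 2L, 1L)), NA_integer_)

  ## long vectors of alternating exon/intron part widths per gene
  p_per_gene <- 2L * n_ex - 1L
  gidx <- rep(seq_len(n_genes), p_per_gene)
  part <- sequence(p_per_gene)
  is_ex <- part %% 2L == 1L
  widths <- numeric(length(gidx))
  widths[is_ex] <- pmax(round(stats::rlnorm(sum(is_ex), log(200), 0.35)), 50)
  widths[!is_ex] <- pmax(round(stats::rlnorm(sum(!is_ex),
                                             rep(intron_mu, pmax(n_ex - 1L, 0)),
                                             sd_part)), 30)
  span <- rowsum(widths, gidx)[, 1]

  genes_per_chrom <- 100L
  chrom_idx <- (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L
  chrom <- sprintf("chr%s_%d", prefix, chrom_idx)
  within <- stats::ave(span + 2000, chrom_idx, FUN = cumsum)
  gene_start <- as.integer(1000 + within - (span + 2000))

  cs <- cumsum(widths)
  base <- (cs - widths)[!duplicated(gidx)]
  rel_start <- (cs - widths) - rep(base, p_per_gene)
  abs_start <- rep(gene_start, p_per_gene) + rel_start
  abs_end <- abs_start + widths

  ex_rows <- data.frame(
    gene = gidx[is_ex], exon_no = (part[is_ex] + 1L) %/% 2L,
    start = as.integer(abs_start[is_ex]), end = as.integer(abs_end[is_ex]))
  strand <- rep(c("+", "-"), length.out = n_genes)

  t1 <- data.frame(
    transcript_id = sprintf("%s.t1", gene_id[ex_rows$gene]),
    gene_id = gene_id[ex_rows$gene], chrom = chrom[ex_rows$gene],
    strand = strand[ex_rows$gene], start = ex_rows$start, end = ex_rows$end,
    stringsAsFactors = FALSE)
  keep2 <- alt[ex_rows$gene] & ex_rows$exon_no != skip_exon[ex_rows$gene]
  t2 <- t1[keep2, , drop = FALSE]
  t2$transcript_id <- sub("\\.t1$", ".t2", t2$transcript_id)
  exons <- rbind(t1, t2)
  ann <- .build_annotation(exons = exons, cds = exons)
  ann$source_format <- "simulated"
  attr(ann, "truth") <- data.frame(
    gene_id = gene_id, n_exons = n_ex, is_multi_exon = n_ex >= 2L,
    alt = alt, skip_exon = skip_exon, intron_mu = intron_mu, p_alt = p_alt,
    chrom = chrom, strand = strand, stringsAsFactors = FALSE)
  ann
}

## Junction read counts + coverage for one species given its catalog.
## Returns list(junctions, coverage, gene_truth) -- all data.frames.
.simulate_species_reads <- function(ann, expr, psi, read_rate) {
  truth <- attr(ann, "truth")
  ex <- ann$exons
  ex <- ex[grepl("\\.t1$", ex$transcript_id), , drop = FALSE]
  ex <- ex[order(ex$gene_id, ex$start), ]

  ## adjacent-exon junction intervals of the full-length transcript
  same <- ex$gene_id[-1] == ex$gene_id[-nrow(ex)]
  jstart <- ex$end[-nrow(ex)][same]
  jend <- ex$start[-1][same]
  jgene <- ex$gene_id[-nrow(ex)][same]
  exon_no <- stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)
  jno <- exon_no[-nrow(ex)][same]  # junction i joins exon i and i+1

  gi <- match(jgene, truth$gene_id)
  lam <- expr[gi] * read_rate
  skip_of <- truth$skip_exon[gi]
  is_event <- !is.na(skip_of) & (jno == skip_of - 1L | jno == skip_of)
  counts <- integer(length(lam))
  counts[!is_event] <- stats::rpois(sum(!is_event), lam[!is_event])
  counts[is_event] <- stats::rpois(sum(is_event),
                                   lam[is_event] * psi[gi[is_event]])

  ## skipping junctions: donor of exon (k-1), acceptor of exon (k+1)
  alt_i <- which(truth$alt)
  sk <- truth$skip_exon[alt_i]
  key <- paste(truth$gene_id[alt_i], sk - 1L)
  jkey <- paste(jgene, jno)
  left <- match(key, jkey)           # junction (k-1 -> k): start is the donor
  right <- match(paste(truth$gene_id[alt_i], sk), jkey)
  skip_start <- jstart[left]
  skip_end <- jend[right]
  skip_counts <- stats::rpois(length(alt_i),
                              expr[alt_i] * read_rate * (1 - psi[alt_i]))

  jdf <- data.frame(
    chrom = c(truth$chrom[gi], truth$chrom[alt_i]),
    start = c(jstart, skip_start), end = c(jend, skip_end),
    name = "sim",
    count = c(counts, skip_counts),
    strand = c(truth$strand[gi], truth$strand[alt_i]),
    stringsAsFactors = FALSE)
  jdf <- jdf[jdf$count > 0, , drop = FALSE]
  jdf$name <- sprintf("j%d", seq_len(nrow(jdf)))
  rownames(jdf) <- NULL

  depth <- round(expr)
  cov <- data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                    depth = depth[match(ex$gene_id, truth$gene_id)],
                    stringsAsFactors = FALSE)
  cov <- cov[cov$depth > 0, , drop = FALSE]
  rownames(cov) <- NULL

  ## expected junction-usage entropy of the skipping cluster
  h_true <- rep(0, nrow(truth))
  if (length(alt_i)) {
    ps <- psi[alt_i]
    f <- cbind(ps, ps, 1 - ps) / (1 + ps)
    h_true[alt_i] <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  }
  gene_truth <- data.frame(truth, expression = depth, psi = psi,
                           entropy_true = h_true, stringsAsFactors = FALSE)
  list(junctions = jdf, coverage = cov, gene_truth = gene_truth)
}

#' Simulate a full cross-species fixture bundle
#'
#' Generates, for each species on a (simulated or provided) phylogeny: a
#' gene catalog, junction read counts, an exon coverage track, a complexity
#' trait (CTN) and per-gene ground truth. The alternatively spliced fraction
#' of each species follows its scaled log complexity through
#' `complexity_slope`; junction counts are Poisson in expression, so
#' detection saturates with expression exactly as the binning correction
#' assumes. Identical (config, seed) pairs give identical bundles, and
#' byte-identical files when `out_dir` is set.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param out_dir Optional directory; when given, writes per-species
#'   `<sp>.junc`, `<sp>.gtf`, `<sp>.bedgraph`, plus `tree.nwk`,
#'   `traits.tsv` and `manifest.yaml`.
#' @return A `species_set` list: config, tree, traits (species, ctn,
#'   frac_alt, true_asp, true_asl, mean intron size...), species (named list
#'   with annotation, junctions, coverage, gene_truth), paths (if written).
#' @export
simulate_species_set <- function(config, seed = config$seed, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_species

  tree <- if (config$tree_mode == "provided") {
    stopifnot(inherits(config$tree, "phylo"))
    config$tree
  } else {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n))
    tr
  }

  rng <- log(config$complexity_range)
  root <- mean(rng)
  lct <- simulate_traits_on_tree(tree, config$brownian_sigma,
                                 config$lambda_true, root = root)
  ctn <- round(pmin(pmax(exp(lct), config$complexity_range[1]),
                    config$complexity_range[2]))
  c_scaled <- if (diff(rng) > 0) (log(ctn) - rng[1]) / diff(rng)
              else rep(0.5, n)
  frac_alt <- config$frac_alt_base +
    config$complexity_slope * (c_scaled - 0.5)
  if (any(frac_alt < 0 | frac_alt > 1)) {
    warning("alternatively spliced fraction clipped to [0, 1]")
    frac_alt <- pmin(pmax(frac_alt, 0), 1)
  }
  intron_mu_sp <- config$intron_meanlog +
    config$intron_ctn_slope * (c_scaled - 0.5) +
    stats::rnorm(n, 0, config$intron_species_sd)

  species <- tree$tip.label
  out <- vector("list", n)
  names(out) <- species
  tr_rows <- vector("list", n)
  for (s in seq_len(n)) {
    ann <- simulate_gene_catalog(
      config$n_genes, intron_meanlog = intron_mu_sp[s],
      intron_sdlog = config$intron_sdlog,
      single_exon_frac = config$single_exon_frac,
      frac_alt = frac_alt[s], intron_coupling = config$intron_coupling,
      mean_exons = config$mean_exons, prefix = sprintf("%s_", species[s]))
    truth <- attr(ann, "truth")
    expr <- stats::rlnorm(config$n_genes, config$expr_meanlog,
                          config$expr_sdlog)
    psi <- stats::rbeta(config$n_genes, config$dirichlet_conc,
                        config$dirichlet_conc)
    reads <- .simulate_species_reads(ann, expr, psi, config$read_rate)
    out[[s]] <- c(list(annotation = ann), reads)

    multi <- truth$is_multi_exon
    gt <- reads$gene_truth
    tr_rows[[s]] <- data.frame(
      species = species[s], ctn = ctn[s], frac_alt = frac_alt[s],
      true_asp = mean(truth$alt[multi]),
      true_asl = mean(gt$entropy_true[multi]),
      data_quantity = sum(reads$junctions$count),
      stringsAsFactors = FALSE)
  }
  traits <- do.call(rbind, tr_rows)
  rownames(traits) <- NULL

  bundle <- structure(list(config = config, tree = tree, traits = traits,
                           species = out), class = "species_set")
  if (!is.null(out_dir)) bundle <- .write_species_set(bundle, out_dir)
  bundle
}

#' @export
print.species_set <- function(x, ...) {
  cat("species_set:", nrow(x$traits), "species,",
      x$config$n_genes, "genes each; CTN",
      paste(range(x$traits$ctn), collapse = "-"),
      sprintf("; true ASP %.2f-%.2f\n",
              min(x$traits$true_asp), max(x$traits$true_asp)))
  invisible(x)
}

.write_species_set <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(out_dir, "tree.nwk"),
                traits = file.path(out_dir, "traits.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  ape::write.tree(bundle$tree, paths$tree)
  utils::write.table(bundle$traits, paths$traits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (sp in names(bundle$species)) {
    b <- bundle$species[[sp]]
    write_junction_file(b$junctions, file.path(out_dir, paste0(sp, ".junc")))
    write_gtf(b$annotation, file.path(out_dir, paste0(sp, ".gtf")))
    write_bedgraph(b$coverage, file.path(out_dir, paste0(sp, ".bedgraph")))
  }
  cfg <- bundle$config
  cfg$tree <- NULL
  manifest <- list(
    package = "spliceprev",
    config = lapply(unclass(cfg), function(v)
      if (is.numeric(v)) as.numeric(v) else as.character(v)),
    species = names(bundle$species),
    files = c("tree.nwk", "traits.tsv",
              paste0(rep(names(bundle$species), each = 3),
                     c(".junc", ".gtf", ".bedgraph"))))
  yaml::write_yaml(manifest, paths$manifest)
  bundle$paths <- c(paths, dir = out_dir)
  bundle
}

#' Three study-shaped simulation configurations
#'
#' Returns configurations mirroring the three comparative designs the
#' analysis is built around: Set 1 — large introns (gene-level means around
#' 2-42 kb) and widely varying complexity (CTN 50-216) with a negative
#' intron-complexity coupling; Set 2 — small introns (about 0.7-3 kb) and
#' widely varying complexity (CTN 22-119); Set 3 — fixed complexity
#' (CTN 59) with strongly varying intron size (about 0.3-14 kb).
#'
#' @param seed Base seed stored in each configuration.
#' @param n_genes Genes per species (shared by the three sets).
#' @return Named list of three `sim_config`s (set1, set2, set3).
#' @export
make_study_designs <- function(seed = 1, n_genes = 1500) {
  ## lognormal location giving a target mean intron size at dispersion sdlog
  mu_for_mean <- function(target, sdlog) log(target) - sdlog^2 / 2
  list(
    set1 = sim_config(n_species = 14, complexity_range = c(50, 216),
                      intron_meanlog = mu_for_mean(9200, 1),
                      intron_sdlog = 1, intron_species_sd = 0.9,
                      intron_ctn_slope = -0.6, n_genes = n_genes,
                      seed = seed),
    set2 = sim_config(n_species = 14, complexity_range = c(22, 119),
                      intron_meanlog = mu_for_mean(1450, 0.8),
                      intron_sdlog = 0.8, intron_species_sd = 0.28,
                      intron_ctn_slope = -0.2, n_genes = n_genes,
                      seed = seed + 1),
    set3 = sim_config(n_species = 12, complexity_range = c(59, 59),
                      brownian_sigma = 0, complexity_slope = 0,
                      intron_meanlog = mu_for_mean(2050, 1),
                      intron_sdlog = 1, intron_species_sd = 1.1,
                      n_genes = n_genes, seed = seed + 2))
}
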