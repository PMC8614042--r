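#' Pipeline configuration
#'
#' Collects paths and parameters for a full cross-species run. All defaults
#' equal the analysis protocol's stated parameters: intron clusters at most
#' 500 kb with at least 30 supporting reads, expression rule depth > 2,
#' FPKM threshold 0.1, event support 5 reads, plateau tolerance 1e-4,
#' saturation at 4 plateau bins, bin sizes 100 and 500.
#'
#' @param junc_files Named character vector (by species) of junc file paths.
#' @param annotation_files Named character vector of GTF/GFF3 paths.
#' @param coverage_files Named character vector of bedGraph paths.
#' @param traits_file TSV with a `species` column and a `ctn` column.
#' @param tree_file Newick tree file (optional; enables PGLS).
#' @param mode Counting mode (junction, isoform, event).
#' @param bin_sizes Bin sizes for the saturation correction.
#' @param max_intron_len,min_cluster_reads Clustering parameters.
#' @param min_depth,fpkm_threshold,min_event_reads Expression thresholds.
#' @param plateau_tol,saturation_bins Plateau parameters.
#' @param methods Correlation methods to run.
#' @param seed Seed recorded in the manifest.
#' @param out_dir Output directory (NULL for in-memory results only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(junc_files, annotation_files, coverage_files,
                            traits_file, tree_file = NULL,
                            mode = "junction", bin_sizes = c(100, 500),
                            max_intron_len = 500000, min_cluster_reads = 30,
                            min_depth = 2, fpkm_threshold = 0.1,
                            min_event_reads = 5, plateau_tol = 1e-4,
                            saturation_bins = 4,
                            methods = c("spearman", "linreg", "pgls"),
                            seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

## Analyse one species: cluster junctions, assign to genes, build records.
.analyze_one_species <- function(junctions, annotation, coverage,
                                 max_intron_len = 500000,
                                 min_cluster_reads = 30, min_depth = 2) {
  cl <- cluster_junctions(junctions, max_intron_len = max_intron_len,
                          min_cluster_reads = min_cluster_reads)
  cl <- assign_and_filter_clusters(cl, annotation)
  gene_splicing_records(annotation, cl, coverage = coverage,
                        min_depth = min_depth)
}

#' Analyse an in-memory species set
#'
#' Runs the junction-mode protocol over every species of a bundle (as
#' produced by [simulate_species_set()] or assembled from files by
#' [run_pipeline()]): junction clustering, gene assignment, per-gene
#' records, all-gene ASP/ASL, binned depth-corrected PASP/PASL, intron
#' statistics, and the cross-species correlation grid of every measure
#' against complexity and the intron-size statistics.
#'
#' @param bundle A `species_set`.
#' @param bin_size Genes per expression bin for the saturation correction.
#' @param max_intron_len,min_cluster_reads,min_depth Protocol parameters.
#' @param methods Correlation methods (subset of spearman, linreg, pgls,
#'   partial_spearman).
#' @param predictors Trait columns to correlate the splicing measures with.
#' @return List: `summary` (per-species data.frame), `grid` (correlation
#'   rows), `records` (named list of per-gene tables), `tree`.
#' @export
analyze_species_set <- function(bundle, bin_size = 100,
                                max_intron_len = 500000,
                                min_cluster_reads = 30, min_depth = 2,
                                methods = c("spearman", "linreg", "pgls"),
                                predictors = c("ctn", "mean_intron_size",
                                               "cds_density",
                                               "intron_density")) {
  stopifnot(inherits(bundle, "species_set") || is.list(bundle))
  species <- names(bundle$species)
  records <- list()
  rows <- list()
  for (sp in species) {
    b <- bundle$species[[sp]]
    rec <- .analyze_one_species(b$junctions, b$annotation, b$coverage,
                                max_intron_len, min_cluster_reads, min_depth)
    records[[sp]] <- rec
    sat_asp <- tryCatch(
      estimate_splicing_saturation(rec, bin_size, "asp"),
      error = function(e) NULL)
    sat_asl <- tryCatch(
      estimate_splicing_saturation(rec, bin_size, "asl"),
      error = function(e) NULL)
    gstats <- genome_intron_stats(gene_intron_table(b$annotation))
    rows[[sp]] <- data.frame(
      species = sp,
      asp = species_asp(rec, "junction"),
      asl = species_asl(rec, "junction"),
      pasp = if (is.null(sat_asp)) NA_real_ else sat_asp$estimate,
      pasl = if (is.null(sat_asl)) NA_real_ else sat_asl$estimate,
      asp_plateau = if (is.null(sat_asp)) NA_real_
                    else sat_asp$plateau$plateau_mean,
      saturated = if (is.null(sat_asp)) NA else sat_asp$plateau$saturated,
      mean_intron_size = gstats$mean_intron_size,
      cds_density = gstats$cds_density,
      intron_density = gstats$intron_density,
      n_genes_used = sum(rec$is_multi_exon & rec$is_expressed),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(bundle$traits))
    summary <- merge(bundle$traits, summary, by = "species", sort = FALSE)

  grid <- correlation_grid(summary, tree = bundle$tree, methods = methods,
                           predictors = intersect(predictors,
                                                  names(summary)))
  list(summary = summary, grid = grid, records = records,
       tree = bundle$tree)
}

#' Cross-species correlation grid
#'
#' Every splicing measure (asp, asl, pasp, pasl — those present) against
#' every predictor, for each requested method. `partial_spearman` rows
#' control complexity-intron confounding: measure vs `ctn` controlling
#' `mean_intron_size` and vice versa.
#'
#' @param summary Per-species data.frame (needs a `species` column).
#' @param tree `phylo` tree (required for method "pgls").
#' @param measures Splicing measure columns to use.
#' @param predictors Predictor columns.
#' @param methods Methods to run.
#' @return data.frame: measure, predictor, method, control, estimate,
#'   adj_r2, p, lambda, n.
#' @export
correlation_grid <- function(summary, tree = NULL,
                             measures = c("asp", "asl", "pasp", "pasl"),
                             predictors = c("ctn", "mean_intron_size",
                                            "cds_density", "intron_density"),
                             methods = c("spearman", "linreg", "pgls")) {
  measures <- intersect(measures, names(summary))
  predictors <- intersect(predictors, names(summary))
  rows <- list()
  add <- function(measure, predictor, method, control, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, predictor = predictor, method = method,
      control = control, estimate = res$estimate, adj_r2 = res$adj_r2,
      p = res$p_value, lambda = res$lambda_hat, n = res$n,
      stringsAsFactors = FALSE)
  }
  df <- summary
  if (is.null(df$species)) stop("summary needs a species column")
  for (m in measures) for (pr in predictors) {
    ok <- stats::complete.cases(df[[m]], df[[pr]])
    if (sum(ok) < 3) next
    x <- df[[pr]][ok]; y <- df[[m]][ok]
    for (meth in methods) {
      res <- tryCatch(switch(meth,
        spearman = spearman_correlation(x, y),
        linreg = linear_regression(x, y),
        pgls = {
          if (is.null(tree)) stop("pgls requires a tree")
          .pgls_pair(df[ok, , drop = FALSE], m, pr, tree)
        },
        partial_spearman = NULL),
        error = function(e) NULL)
      if (!is.null(res)) add(m, pr, meth, NA_character_, res)
    }
  }
  if ("partial_spearman" %in% methods &&
      all(c("ctn", "mean_intron_size") %in% predictors)) {
    for (m in measures) {
      ok <- stats::complete.cases(df[[m]], df$ctn, df$mean_intron_size)
      res1 <- tryCatch(partial_spearman(df$ctn[ok], df[[m]][ok],
                                        df$mean_intron_size[ok]),
                       error = function(e) NULL)
      if (!is.null(res1)) add(m, "ctn", "partial_spearman",
                              "mean_intron_size", res1)
      res2 <- tryCatch(partial_spearman(df$mean_intron_size[ok],
                                        df[[m]][ok], df$ctn[ok]),
                       error = function(e) NULL)
      if (!is.null(res2)) add(m, "mean_intron_size", "partial_spearman",
                              "ctn", res2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from files
#'
#' Reads per-species junction files, annotations and coverage tracks, the
#' trait table and (optionally) the tree, then runs [analyze_species_set()]
#' at each configured bin size. Species present in the trait table but
#' lacking junction files are excluded with a warning. With `out_dir` set,
#' writes `species_summary.tsv`, `correlation_grid.tsv`, per-bin-size bin
#' tables and a `run_manifest.yaml` recording every parameter.
#'
#' @param config A [pipeline_config()].
#' @return List: `summary`, `grids` (one correlation grid per bin size),
#'   `records`, `tree`, `config`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  traits <- utils::read.table(config$traits_file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (is.null(traits$species)) stop("traits file needs a 'species' column")
  species <- traits$species
  have <- species %in% names(config$junc_files) &
    species %in% names(config$annotation_files) &
    species %in% names(config$coverage_files)
  if (any(!have)) {
    warning("species without input files excluded: ",
            paste(species[!have], collapse = ", "))
    species <- species[have]
  }
  if (!length(species)) stop("no species with complete inputs")

  bundle <- list(
    traits = traits[traits$species %in% species, , drop = FALSE],
    tree = if (!is.null(config$tree_file)) ape::read.tree(config$tree_file)
           else NULL,
    species = stats::setNames(lapply(species, function(sp) list(
      junctions = read_junction_file(config$junc_files[[sp]]),
      annotation = read_gene_annotation(config$annotation_files[[sp]]),
      coverage = read_bedgraph(config$coverage_files[[sp]]))), species))

  methods <- config$methods
  if (is.null(bundle$tree)) methods <- setdiff(methods, "pgls")
  results <- list()
  for (bs in config$bin_sizes) {
    results[[as.character(bs)]] <- analyze_species_set(
      bundle, bin_size = bs, max_intron_len = config$max_intron_len,
      min_cluster_reads = config$min_cluster_reads,
      min_depth = config$min_depth, methods = methods)
  }
  first <- results[[1]]
  out <- list(summary = first$summary,
              grids = lapply(results, `[[`, "grid"),
              records = first$records, tree = bundle$tree, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$summary,
                       file.path(config$out_dir, "species_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (bs in names(out$grids))
      utils::write.table(out$grids[[bs]],
                         file.path(config$out_dir,
                                   sprintf("correlation_grid_bin%s.tsv", bs)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$out_dir <- NULL
    yaml::write_yaml(
      list(package = "spliceprev",
           parameters = lapply(unclass(cfg), function(v)
             if (is.null(v)) NULL
             else if (is.numeric(v)) as.numeric(v) else as.character(v)),
           species = species),
      file.path(config$out_dir, "run_manifest.yaml"))
  }
  invisible(out)
}
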