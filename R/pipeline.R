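#' Default pipeline configuration
#'
#' Paths may be NULL when `simulate = TRUE`, in which case the simulator
#' generates reference, scaffolds, VCF and genes inside the run directory.
#'
#' @param reference,scaffolds,vcf,genes input file paths (FASTA / VCF).
#' @param window_sizes window sizes (bp) for painting.
#' @param min_qual minimum VCF site quality.
#' @param k,max_occ aligner seed size and repeat-masking threshold.
#' @param min_coverage,min_identity gene-locator acceptance thresholds.
#' @param region QTL region string, or NULL to skip the zoom stage.
#' @param samples VCF sample names (offspring, parent A, parent B).
#' @param simulate logical: generate the synthetic dataset first.
#' @param sim a [sim_config()] used when `simulate` is TRUE.
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reference = NULL, scaffolds = NULL, vcf = NULL,
                            genes = NULL,
                            window_sizes = c(50000L, 100000L),
                            min_qual = 30, k = 15L, max_occ = 50L,
                            min_coverage = 0.5, min_identity = 0.8,
                            region = NULL,
                            samples = c("offspring", "parent_a", "parent_b"),
                            simulate = FALSE, sim = sim_config(seed = seed),
                            seed = 1L) {
  cfg <- list(reference = reference, scaffolds = scaffolds, vcf = vcf,
              genes = genes, window_sizes = as.integer(window_sizes),
              min_qual = min_qual, k = as.integer(k),
              max_occ = as.integer(max_occ),
              min_coverage = min_coverage, min_identity = min_identity,
              region = region, samples = samples,
              simulate = isTRUE(simulate), sim = sim, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map 1:1 onto [pipeline_config()] arguments; a `sim` block
#' maps onto [sim_config()] arguments.  The config round-trips through
#' [write_pipeline_config()] losslessly.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  y <- y[!vapply(y, is.null, logical(1))]
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_args)) cfg$sim <- do.call(sim_config, sim_args)
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: (1) simulate (optional), (2) place scaffolds on the reference,
#' (3) build pseudomolecules + AGP, (4) assembly statistics, (5) locate
#' gene queries, (6) paint the offspring genome from the trio VCF at each
#' window size, (7) zoom into the QTL region.  All tabular outputs are TSV;
#' a JSON manifest records the config hash, seed, per-stage status and key
#' counts.  Reruns with the same config and inputs are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created).
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(name, ...) {
    info <- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
    stages[[name]] <<- c(list(status = "complete"), info)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)

  if (config$simulate) {
    sim_dir <- file.path(out_dir, "simulated")
    ds <- simulate_dataset(config$sim, sim_dir)
    config$reference <- ds$paths$reference
    config$scaffolds <- ds$paths$scaffolds
    config$vcf <- ds$paths$vcf
    config$genes <- ds$paths$genes
    note("simulate", chromosomes = config$sim$n_chrom,
         scaffolds = length(ds$scaffolds$scaffolds),
         catalog_sites = length(ds$founders$catalog$pos))
  } else {
    stages[["simulate"]] <- list(status = "skipped")
  }
  for (f in c("reference", "scaffolds", "vcf"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop(sprintf("[inputs] missing %s file: %s", f,
                   if (is.null(config[[f]])) "<unset>" else config[[f]]),
           call. = FALSE)

  reference <- as_genome(config$reference)
  index <- index_reference(reference, k = config$k, max_occ = config$max_occ)
  scaffolds <- as_genome(config$scaffolds)
  placements <- place_scaffolds(scaffolds, index)
  write_placements(placements, file.path(out_dir, "placements.tsv"))
  note("place", placed = nrow(placements),
       unplaced = length(attr(placements, "unplaced")))

  build <- build_pseudomolecules(placements, scaffolds, index)
  Biostrings::writeXStringSet(build$pseudomolecules,
                              file.path(out_dir, "pseudomolecules.fa"))
  write_agp(build, file.path(out_dir, "assembly.agp"))
  writeLines(build$unplaced, file.path(out_dir, "unplaced.txt"))
  note("build", genome_size = build$genome_size,
       unplaced = length(build$unplaced))

  ref_sizes <- stats::setNames(sum(as.numeric(Biostrings::width(reference))),
                               "reference")
  stats_ <- assembly_stats(scaffolds, build, ref_sizes)
  write_stats(stats_, file.path(out_dir, "assembly_stats.tsv"))
  note("stats", n50 = stats_$n50,
       coverage_pct = unname(stats_$coverage_pct[1L]))

  hits <- NULL
  if (!is.null(config$genes) && file.exists(config$genes)) {
    build_index <- index_reference(build$pseudomolecules, k = config$k,
                                   max_occ = config$max_occ)
    hits <- locate_genes(config$genes, build_index,
                         min_coverage = config$min_coverage,
                         min_identity = config$min_identity)
    utils::write.table(hits, file.path(out_dir, "gene_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("locate", genes = nrow(hits), located = sum(!is.na(hits$start)))
  } else stages[["locate"]] <- list(status = "skipped")

  sites <- filter_sites(config$vcf, offspring = config$samples[1L],
                        parent_a = config$samples[2L],
                        parent_b = config$samples[3L],
                        min_qual = config$min_qual)
  sites <- classify_snps(sites)
  utils::write.table(sites, file.path(out_dir, "snp_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chrom_lengths <- stats::setNames(Biostrings::width(reference),
                                   names(reference))
  paintings <- list()
  for (w in config$window_sizes) {
    blocks <- window_paint(sites, chrom_lengths, w)
    utils::write.table(blocks,
                       file.path(out_dir, sprintf("windows_%d.tsv", w)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- composition(blocks)
    utils::write.table(comp,
                       file.path(out_dir, sprintf("composition_%d.tsv", w)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paintings[[as.character(w)]] <- list(blocks = blocks, composition = comp)
  }
  note("paint", snps = nrow(sites), classified = sum(!is.na(sites$class)),
       windows = paste(config$window_sizes, collapse = ","))

  qtl <- NULL
  if (!is.null(config$region)) {
    w0 <- as.character(config$window_sizes[1L])
    qtl <- qtl_report(paintings[[w0]]$blocks, config$region)
    utils::write.table(qtl$segments, file.path(out_dir, "qtl_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("qtl", segments = nrow(qtl$segments))
  } else stages[["qtl"]] <- list(status = "skipped")

  manifest <- list(
    package = "mosaicpaint",
    version = as.character(utils::packageVersion("mosaicpaint")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, placements = placements, build = build,
                 stats = stats_, gene_hits = hits, sites = sites,
                 paintings = paintings, qtl = qtl))
}
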