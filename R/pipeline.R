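#' Default pipeline configuration
#'
#' Returns the full default configuration of [run_pipeline()] as a nested
#' list; any subset of it can be overridden via the `config` argument (a
#' list or a YAML file with the same structure). The synthetic specs default
#' to the study conditions of the diagnostics: a ~1 Mb haploid genome at
#' 5.7% heterozygosity with 80% of its span separated, 36x total short-read
#' depth, and the fixed 18 +- 6 coverage windows.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @export
pipeline_defaults <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "map", "coverage", "pc", "ortholog",
               "cq", "expression", "subtraction"),
    genome = list(),                      # genome_sim_spec() overrides
    reads = list(),                       # read_sim_spec() overrides
    mapper = list(max_mismatches = 8, k = 31, fragment_bounds = c(100, 600)),
    classes = list(center = 18, halfwidth = 6, estimation = "fixed"),
    pc = list(density_threshold = 4.5, anchor_k = 21, max_anchor_gap = 500,
              min_extension = 1000),
    cq = list(span_length = 1000, cq_threshold = 0.01, min_male = 10,
              depth_per_sex = 20),
    expression = list(mean_rpkm_target = 32, sdlog = 1.6, total_reads = 2e6,
                      n_silent_families = 1, family_size = 5),
    subtraction = list(n_reads = 20000, foreign_fraction = 0.15,
                       max_mismatches = 2))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full diagnostics pipeline on a synthetic genome
#'
#' Executes the enabled stages in dependency order — simulate, map,
#' coverage, pc, ortholog, cq, expression, subtraction — on a seeded
#' synthetic diploid genome, and consolidates each stage's summary into one
#' report. Stage toggling removes a section from the report without
#' affecting the others; identical configurations and seeds reproduce
#' identical reports.
#'
#' @param config A nested list (see [pipeline_defaults()]) or a YAML file
#'   path with the same structure.
#' @param out_dir Optional output directory: per-stage TSVs plus a
#'   consolidated `report.json` are written there.
#' @return An `hd_report` list with one element per executed stage and a
#'   `summary` element collecting the stage glances.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  stages <- cfg$stages
  need <- function(stage, dep) {
    hd_assert(dep %in% names(report),
              paste0("stage '", stage, "' requires stage '", dep,
                     "' to be enabled"))
  }
  report <- list(config = cfg)
  seed <- cfg$seed

  if ("simulate" %in% stages) {
    gspec <- do.call(genome_sim_spec,
                     merge_config(list(seed = seed), cfg$genome))
    genome <- simulate_diploid_genome(gspec)
    assembly <- simulate_assembly(genome)
    report$simulate <- list(genome = genome, assembly = assembly,
                            heterozygosity = realized_heterozygosity(genome))
  }

  if ("map" %in% stages) {
    need("map", "simulate")
    assembly <- report$simulate$assembly
    rspec <- do.call(read_sim_spec,
                     merge_config(list(seed = seed + 1L), cfg$reads))
    reads <- simulate_reads(report$simulate$genome, rspec)
    idx <- build_index(assembly$contigs, k = cfg$mapper$k)
    best1 <- map_pairs(reads, idx, mapper_config(
      "best_one", max_mismatches = cfg$mapper$max_mismatches,
      fragment_bounds = cfg$mapper$fragment_bounds, seed = seed + 2L))
    best4 <- map_pairs(reads, idx, mapper_config(
      "best_k", max_mismatches = cfg$mapper$max_mismatches,
      fragment_bounds = cfg$mapper$fragment_bounds, seed = seed + 3L))
    report$map <- list(reads = reads, read_spec = rspec,
                       best1 = best1, best4 = best4,
                       mapped_fraction = dplyr::n_distinct(best1$pair_id) /
                         nrow(reads))
  }

  if ("coverage" %in% stages) {
    need("coverage", "map")
    prof <- depth_histogram(report$map$best1)
    classes <- classify_contigs(prof, do.call(coverage_classes, cfg$classes))
    gs <- estimate_genome_size(classes)
    stats <- assembly_stats(classes, genome_size = gs$genome_size)
    report$coverage <- list(profile = prof, classes = classes,
                            genome_size = gs, stats = stats)
  }

  if ("pc" %in% stages) {
    need("pc", "coverage")
    counts <- doubly_mapped(report$map$best4)
    pcc <- do.call(pc_config, cfg$pc)
    pcs <- detect_pcs(counts, pcc)
    aln <- pc_alignments(pcs, report$simulate$assembly, pcc)
    graph <- build_walks(aln, pcc)
    report$pc <- list(counts = counts, pcs = pcs, alignments = aln,
                      graph = graph, span = pc_span_summary(pcs))
  }

  if ("ortholog" %in% stages) {
    need("ortholog", "pc")
    hits <- simulate_gene_hits(report$simulate$assembly)
    inst <- ingest_gene_hits(hits, report$coverage$classes)
    xtab <- instance_crosstab(inst)
    assoc <- association_test(xtab)
    triage <- triage_missing_genes(inst, report$pc$pcs, report$map$best1,
                                   report$coverage$classes)
    report$ortholog <- list(instances = inst, crosstab = xtab,
                            association = assoc, triage = triage)
  }

  if ("cq" %in% stages) {
    need("cq", "simulate")
    genome <- report$simulate$genome
    cqc <- cq_config(cfg$cq$span_length, cfg$cq$cq_threshold, cfg$cq$min_male)
    mk <- function(sex, s) {
      simulate_reads(genome, read_sim_spec(
        depth_total = cfg$cq$depth_per_sex, error_rate = 0,
        layout = "SINGLE", sex = sex, seed = s))
    }
    cq <- cq_analysis(report$simulate$assembly$contigs,
                      mk("FEMALE", seed + 4L), mk("MALE", seed + 5L),
                      mask = NULL, config = cqc, k = cfg$mapper$k)
    report$cq <- list(cq = cq, m_locus = report$simulate$assembly$m_locus_contig)
  }

  if ("expression" %in% stages) {
    need("expression", "simulate")
    tx <- transcript_sequences(report$simulate$genome)
    ecfg <- cfg$expression
    fam_size <- ecfg$family_size
    n_fam <- floor(length(tx) / fam_size)
    families <- tibble::tibble(
      family = paste0("fam", rep(seq_len(n_fam), each = fam_size)),
      transcript_id = names(tx)[seq_len(n_fam * fam_size)])
    silent <- families$transcript_id[
      families$family %in% paste0("fam", seq_len(ecfg$n_silent_families))]
    counts <- simulate_expression_counts(
      tx, mean_rpkm_target = ecfg$mean_rpkm_target, sdlog = ecfg$sdlog,
      zero_inflated = silent, total_reads = ecfg$total_reads,
      seed = seed + 6L)
    expr <- quantify_expression(counts)
    fams <- family_report(expr, families)
    report$expression <- list(expression = expr, families = fams,
                              silent = unique(families$family[
                                families$transcript_id %in% silent]))
  }

  if ("subtraction" %in% stages) {
    need("subtraction", "simulate")
    scfg <- cfg$subtraction
    n_foreign <- round(scfg$n_reads * scfg$foreign_fraction)
    n_host <- scfg$n_reads - n_foreign
    gspec <- report$simulate$genome$spec
    haploid <- as.numeric(gspec$n_chromosomes) * gspec$chrom_length
    depth_needed <- ceiling(n_host * 150 / haploid) + 1
    host <- simulate_reads(report$simulate$genome, read_sim_spec(
      depth_total = depth_needed, error_rate = 0, layout = "SINGLE",
      seed = seed + 7L))
    mix <- withr::with_seed(seed + 9L, {
      host <- host[sample.int(nrow(host), min(n_host, nrow(host))), ]
      host$id <- paste0("host", seq_len(nrow(host)))
      mix <- dplyr::bind_rows(host, random_reads(n_foreign, seed = seed + 8L))
      mix[sample.int(nrow(mix)), ]
    })
    sub <- cascade_filter(mix, transcript_sequences(report$simulate$genome),
                          report$simulate$assembly$contigs,
                          mapper_config(max_mismatches = scfg$max_mismatches))
    report$subtraction <- sub
  }

  report$summary <- consolidate_report(report)
  class(report) <- "hd_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

consolidate_report <- function(report) {
  s <- list()
  if (!is.null(report$coverage)) {
    s$classes <- glance(report$coverage$classes)
    s$genome_size <- tibble::as_tibble(report$coverage$genome_size)
    s$assembly_stats <- report$coverage$stats
  }
  if (!is.null(report$pc)) {
    s$doubly_mapped <- glance(report$pc$counts)
    s$pcs <- glance(report$pc$pcs)
    s$walks <- glance(report$pc$graph)
  }
  if (!is.null(report$ortholog)) {
    s$crosstab <- glance(report$ortholog$crosstab)
    s$association <- glance(report$ortholog$association)
  }
  if (!is.null(report$cq)) s$cq <- glance(report$cq$cq)
  if (!is.null(report$expression)) {
    s$expression <- glance(report$expression$expression)
  }
  if (!is.null(report$subtraction)) {
    s$subtraction <- glance(report$subtraction)
  }
  s
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, name))
  }
  if (!is.null(report$coverage)) w(report$coverage$classes, "contig_classes.tsv")
  if (!is.null(report$pc)) {
    w(report$pc$alignments, "paired_contigs.tsv")
    w(report$pc$graph$walks |> mutate(contigs = purrr::map_chr(
      .data$contigs, paste, collapse = ",")), "walks.tsv")
  }
  if (!is.null(report$ortholog)) {
    w(report$ortholog$crosstab, "ortholog_crosstab.tsv")
    w(report$ortholog$triage, "missing_gene_triage.tsv")
  }
  if (!is.null(report$cq)) w(report$cq$cq, "cq_spans.tsv")
  if (!is.null(report$expression)) {
    w(report$expression$expression, "expression.tsv")
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.hd_report <- function(x, ...) {
  cat("<hd_report> stages:",
      paste(setdiff(names(x), c("config", "summary")), collapse = ", "), "\n")
  for (nm in names(x$summary)) {
    cat("--", nm, "--\n")
    print(x$summary[[nm]])
  }
  invisible(x)
}
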