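#' Configuration for the end-to-end synthetic pipeline
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] describing the synthetic experiment.
#' @param q_threshold FDR threshold for target calling (default 0.1).
#' @param alpha Fisher significance threshold for the enhancer screen
#'   (default 0.001).
#' @param genotypes Data frame (`label`, `n`, `arrest_prob`) for the
#'   simulated screen. The default mirrors a sensitised-background screen:
#'   near-zero arrest in wild type, partial penetrance in the single
#'   mutant, near-complete arrest in the double mutant.
#' @param reference_labels Reference genotypes for the screen.
#' @param score_filter Passed to [rip_enrichment()].
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            q_threshold = 0.1,
                            alpha = 0.001,
                            genotypes = data.frame(
                              label = c("WT", "single_lf", "double_lf"),
                              n = c(300L, 300L, 300L),
                              arrest_prob = c(0.01, 0.2, 0.97),
                              stringsAsFactors = FALSE),
                            reference_labels = c("WT", "single_lf"),
                            score_filter = FALSE) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(out_dir = out_dir, sim = sim, q_threshold = q_threshold,
                 alpha = alpha, genotypes = genotypes,
                 reference_labels = reference_labels,
                 score_filter = score_filter),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic pipeline: simulate, enrich, scan, test
#'
#' Executes the stages in order, writing every intermediate to `out_dir`
#' (counts TSV, UTR FASTA, gene map, family table, truth, enrichment
#' results, target list, site table, density tables) and an end-to-end
#' `report.json`. Downstream stages re-read the files written by earlier
#' stages, so any stage can be resumed from disk. The report is a pure
#' function of the configuration (including its seed).
#'
#' The report contains: the target count with sensitivity/FDR against the
#' planted truth; fold-change summaries of targets versus all transcripts;
#' seed-site density fold changes for all families and for the designated
#' interacting-family subset; a hypergeometric overlap test of the called
#' targets against genes carrying interacting-family sites; and the
#' enhancer-screen table.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config object")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  cfg <- config$sim

  .stage("simulate", {
    ann <- simulate_annotation(cfg)
    cm <- simulate_counts(cfg, ann$truth)
    write_utr_fasta(ann$utrs, p("utrs.fa"))
    write_gene_map_tsv(ann$gene_map, p("gene_map.tsv"))
    write_families_tsv(ann$families, p("families.tsv"))
    write_gene_list(ann$interacting_families, p("interacting_families.txt"))
    write_gene_list(ann$expressed_genes, p("expressed_genes.txt"))
    write_gene_list(ann$truth$bound_genes, p("truth_bound_genes.txt"))
    write_sites_tsv(ann$truth$planted_sites, p("truth_sites.tsv"))
    write_counts_tsv(cm, p("counts.tsv"))
    pheno <- simulate_phenotypes(
      config$genotypes,
      rng_seed = (cfg$rng_seed + 2L) %% .Machine$integer.max)
    write_phenotypes_tsv(pheno, p("phenotypes.tsv"))
    message("  ", length(ann$utrs), " isoforms, ",
            nrow(ann$truth$planted_sites), " planted sites, ",
            nrow(cm), " x ", ncol(cm), " counts")
  })

  enr <- .stage("enrich", {
    cm <- read_counts_tsv(p("counts.tsv"))
    gene_map <- read_gene_map_tsv(p("gene_map.tsv"))
    fit <- rip_enrichment(cm, gene_map, q_threshold = config$q_threshold,
                          score_filter = config$score_filter)
    utils::write.table(fit$results, p("enrichment_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_list(fit$targets, p("target_genes.txt"))
    message("  ", length(fit$targets), " target genes at q < ",
            config$q_threshold)
    fit
  })

  dens <- .stage("seedscan", {
    utrs <- read_utr_fasta(p("utrs.fa"))
    gene_map <- read_gene_map_tsv(p("gene_map.tsv"))
    families <- read_families_tsv(p("families.tsv"))
    interacting <- read_gene_list(p("interacting_families.txt"))
    expressed <- read_gene_list(p("expressed_genes.txt"))
    targets <- read_gene_list(p("target_genes.txt"))
    sites <- scan_seed_sites(utrs, families)
    write_sites_tsv(sites, p("sites.tsv"))
    tab_all <- utr_density_table(sites, utrs, gene_map)
    tab_sub <- utr_density_table(sites, utrs, gene_map,
                                 families = interacting)
    .write_tsv(tab_all, p("density_all_families.tsv"))
    .write_tsv(tab_sub, p("density_interacting.tsv"))
    background <- unique(gene_map$gene_id)
    list(all = density_comparison(targets, background, tab_all, expressed),
         subset = density_comparison(targets, background, tab_sub,
                                     expressed),
         sites = sites, gene_map = gene_map, targets = targets)
  })

  ov <- .stage("overlap", {
    gm <- dens$gene_map
    with_site <- unique(gm$gene_id[
      gm$isoform_id %in% dens$sites$isoform_id[
        dens$sites$family %in% read_gene_list(p("interacting_families.txt"))]])
    universe <- unique(gm$gene_id)
    hypergeometric_overlap(length(universe), length(dens$targets),
                           length(with_site),
                           length(intersect(dens$targets, with_site)))
  })

  scr <- .stage("screen", {
    pheno <- read_phenotypes_tsv(p("phenotypes.tsv"))
    enhancer_screen(pheno, config$reference_labels, alpha = config$alpha)
  })

  truth_bound <- read_gene_list(p("truth_bound_genes.txt"))
  tp <- length(intersect(enr$targets, truth_bound))
  report <- list(
    n_genes = cfg$n_genes,
    n_bound_true = length(truth_bound),
    targets = list(
      n_target_genes = length(enr$targets),
      sensitivity = if (length(truth_bound)) tp / length(truth_bound) else
        NA_real_,
      fdr = if (length(enr$targets)) 1 - tp / length(enr$targets) else 0),
    fold_change = enr$fold_change,
    density = list(
      all_families = dens$all[c("mean_density_targets",
                                "mean_density_background", "fold_change")],
      interacting = dens$subset[c("mean_density_targets",
                                  "mean_density_background",
                                  "fold_change")]),
    overlap = unclass(ov),
    screen = scr)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c(
    paste0("rng_seed\t", cfg$rng_seed),
    paste0("q_threshold\t", config$q_threshold),
    paste0("alpha\t", config$alpha),
    paste0("n_genes\t", cfg$n_genes),
    paste0("n_bound\t", cfg$n_bound),
    paste0("ip_effect\t", cfg$ip_effect),
    paste0("nb_dispersion\t", cfg$nb_dispersion))
  writeLines(manifest, p("run_manifest.tsv"))
  invisible(report)
}
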