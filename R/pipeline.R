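#' Assemble and validate a pipeline run configuration
#'
#' Collects input paths, thresholds and tuning parameters for
#' [run_pipeline()], and pre-flight checks them: referenced files must
#' exist, thresholds must be in range, and motif enrichment requires genome,
#' GFF3 and motif files together. The validated configuration is serialized
#' verbatim into the run manifest.
#'
#' @param counts,sample_sheet Paths to the counts and sample sheet TSVs
#'   (required).
#' @param annotations Optional gene-to-GO-term TSV.
#' @param tf_annotations Optional gene-to-TF-family TSV.
#' @param genome,gff,motifs Optional genome FASTA, gene-model GFF3 and motif
#'   dictionary (TSV/JSON; `NULL` with `genome`/`gff` set uses the built-in
#'   dictionary). All three inputs (or the built-in fallback for motifs) are
#'   needed for motif enrichment.
#' @param out_dir Output directory (created if absent).
#' @param fc,fdr,p DEG filter thresholds. Defaults 2, 0.01, 0.01.
#' @param k Number of trajectory clusters. Default 10.
#' @param restarts k-means restarts. Default 25.
#' @param gap_B Reference datasets for the gap statistic; 0 skips the gap
#'   assessment. Default 0.
#' @param gap_k_range Candidate k values for the gap curve.
#' @param strand_mode Motif scanning strand mode. Default "both".
#' @param universe Enrichment background: `"annotation"` (all genes in each
#'   annotation input; default) or `"degs"` (the DEG union).
#' @param promoter_length Promoter window length. Default 1000.
#' @param seed Master seed; per-stage seeds are derived from it. Default 1.
#' @return A validated `pti_config` list.
#' @export
run_config <- function(counts, sample_sheet,
                       annotations = NULL, tf_annotations = NULL,
                       genome = NULL, gff = NULL, motifs = NULL,
                       out_dir = "ptiseq_out",
                       fc = 2, fdr = 0.01, p = 0.01,
                       k = 10, restarts = 25,
                       gap_B = 0, gap_k_range = 1:12,
                       strand_mode = c("both", "given"),
                       universe = c("annotation", "degs"),
                       promoter_length = 1000,
                       seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  universe <- match.arg(universe)
  cfg <- list(counts = counts, sample_sheet = sample_sheet,
              annotations = annotations, tf_annotations = tf_annotations,
              genome = genome, gff = gff, motifs = motifs,
              out_dir = out_dir, fc = fc, fdr = fdr, p = p, k = k,
              restarts = restarts, gap_B = gap_B, gap_k_range = gap_k_range,
              strand_mode = strand_mode, universe = universe,
              promoter_length = promoter_length, seed = as.integer(seed))
  for (field in c("counts", "sample_sheet", "annotations", "tf_annotations",
                  "genome", "gff", "motifs")) {
    path <- cfg[[field]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("config error: %s file '%s' does not exist", field, path))
    }
  }
  if (xor(is.null(cfg$genome), is.null(cfg$gff))) {
    abort("config error: motif enrichment needs both genome and gff")
  }
  if (!(fc > 1)) abort("config error: fc must exceed 1")
  for (th in c("fdr", "p")) {
    if (cfg[[th]] <= 0 || cfg[[th]] > 1) {
      abort(sprintf("config error: %s must be in (0, 1]", th))
    }
  }
  if (k < 1) abort("config error: k must be >= 1")
  structure(cfg, class = "pti_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — read + validate, TMM normalization,
#' per-time-point NB contrasts with BH adjustment, the DEG triple filter and
#' its per-time-point summary, replicate-averaged z-scaled trajectories,
#' k-means clustering (with optional gap-statistic assessment), marker
#' selection, and hypergeometric enrichment for each available annotation
#' class (GO, TF family, promoter motif presence) — writing every stage
#' output as TSV into `out_dir` plus a JSON run manifest. A stage failure
#' aborts with the stage name; a partial manifest is still written.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `manifest`, `results` (in-memory stage
#'   results), `outputs` (named file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pti_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  outputs <- character()
  results <- list()
  stage_counts <- list()
  stages_done <- character()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      # leave a partial manifest behind before propagating
      partial <- build_manifest(config, stage_counts, stages_done,
                                status = sprintf("failed at stage '%s'", name))
      write_manifest_json(partial, out("run_manifest.json"))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  results$input <- run_stage("read", {
    read_counts(config$counts, config$sample_sheet)
  })
  stage_counts$genes <- nrow(results$input$counts)
  stage_counts$samples <- nrow(results$input$samples)
  stages_done <- c(stages_done, "read")

  results$factors <- run_stage("normalize", normalize_tmm(results$input$counts))
  write_tsv_na(results$factors, out("norm_factors.tsv"))
  stages_done <- c(stages_done, "normalize")

  results$contrasts <- run_stage("deg-test", {
    test_all_contrasts(results$input$counts, results$input$samples,
                       factors = results$factors)
  })
  write_tsv_na(results$contrasts, out("contrasts.tsv"))
  stage_counts$contrast_rows <- nrow(results$contrasts)
  stages_done <- c(stages_done, "deg-test")

  results$degs <- run_stage("deg-filter", {
    filter_degs(results$contrasts, fc_threshold = config$fc,
                fdr_max = config$fdr, p_max = config$p)
  })
  write_tsv_na(results$degs, out("deg_list.tsv"))
  tps <- sort(unique(results$input$samples$timepoint_h))
  counts_tbl <- deg_counts(results$degs, timepoints_h = tps)
  summary_tbl <- dplyr::bind_rows(
    counts_tbl,
    tibble(timepoint_h = NA_real_, up = NA_integer_, down = NA_integer_,
           total = attr(counts_tbl, "union_size")))
  write_tsv_na(summary_tbl, out("deg_counts.tsv"))
  stage_counts$degs_union <- deg_union(results$degs)
  stages_done <- c(stages_done, "deg-filter")

  results$traj <- run_stage("zscale", {
    profiles <- expression_profiles(results$input$counts, results$input$samples,
                                    factors = results$factors,
                                    genes = unique(results$degs$gene_id))
    zscale(profiles)
  })
  stage_counts$trajectories <- nrow(results$traj)
  stages_done <- c(stages_done, "zscale")

  if (nrow(results$traj) >= config$k) {
    results$fit <- run_stage("cluster", {
      kmeans_cluster(results$traj, k = config$k,
                     seed = derive_seed(config$seed, "cluster"),
                     n_restarts = config$restarts)
    })
    write_tsv_na(results$fit$assignment, out("clusters.tsv"))
    write_tsv_na(summarize_clusters(results$fit), out("centroids.tsv"))
    zt <- results$traj |>
      left_join(results$fit$assignment, by = "gene_id") |>
      arrange(.data$cluster, .data$gene_id)
    write_tsv_na(zt, out("trajectories_z.tsv"))
    stages_done <- c(stages_done, "cluster")

    if (config$gap_B >= 10) {
      results$gap <- run_stage("gap", {
        gap_statistic(results$traj, k_range = config$gap_k_range,
                      B = config$gap_B,
                      seed = derive_seed(config$seed, "gap"))
      })
      write_tsv_na(results$gap$curve, out("gap_curve.tsv"))
      stages_done <- c(stages_done, "gap")
    }

    results$markers <- run_stage("markers", {
      select_markers(results$fit, results$contrasts)
    })
    write_tsv_na(results$markers, out("markers.tsv"))
    stages_done <- c(stages_done, "markers")
  }

  enrich_one <- function(ann, label) {
    uni <- if (config$universe == "degs") unique(results$degs$gene_id) else NULL
    cells <- cluster_enrichment(results$fit$assignment, ann, universe = uni)
    write_tsv_na(cells, out(sprintf("enrichment_%s.tsv", label)))
    hm <- heatmap_matrix(cells)
    hm_tbl <- dplyr::bind_cols(tibble(term_id = rownames(hm)),
                               as_tibble(as.data.frame(hm)))
    write_tsv_na(hm_tbl, out(sprintf("heatmap_%s.tsv", label)))
    cells
  }

  if (!is.null(config$annotations) && !is.null(results$fit)) {
    results$enrichment_go <- run_stage("enrich-GO", {
      enrich_one(read_annotation_map(config$annotations, class = "GO"), "go")
    })
    stages_done <- c(stages_done, "enrich-GO")
  }
  if (!is.null(config$tf_annotations) && !is.null(results$fit)) {
    results$enrichment_tf <- run_stage("enrich-TF", {
      enrich_one(read_annotation_map(config$tf_annotations, class = "TF-family"),
                 "tf")
    })
    stages_done <- c(stages_done, "enrich-TF")
  }
  if (!is.null(config$genome) && !is.null(results$fit)) {
    results$enrichment_motif <- run_stage("enrich-motif", {
      genome <- read_genome(config$genome)
      models <- read_gene_models(config$gff)
      motifs <- if (is.null(config$motifs)) motif_dictionary() else
        read_motif_table(config$motifs)
      promoters <- extract_promoters(models, genome,
                                     promoter_length = config$promoter_length)
      write_promoters_fasta(promoters, out("promoters.fasta"))
      write_promoters_bed(promoters, out("promoters.bed"))
      presence <- presence_table(promoters, motifs,
                                 strand_mode = config$strand_mode)
      write_tsv_na(presence, out("motif_presence.tsv"))
      ann <- presence |>
        tidyr::pivot_longer(-"gene_id", names_to = "term_id",
                            values_to = "present") |>
        filter(.data$present) |>
        select("gene_id", "term_id") |>
        mutate(class = "motif")
      # universe: every gene with an extracted promoter
      uni <- if (config$universe == "degs") unique(results$degs$gene_id) else
        promoters$gene_id
      cells <- cluster_enrichment(results$fit$assignment, ann, universe = uni)
      write_tsv_na(cells, out("enrichment_motif.tsv"))
      hm <- heatmap_matrix(cells)
      write_tsv_na(dplyr::bind_cols(tibble(term_id = rownames(hm)),
                                    as_tibble(as.data.frame(hm))),
                   out("heatmap_motif.tsv"))
      cells
    })
    stages_done <- c(stages_done, "enrich-motif")
  }

  manifest <- build_manifest(config, stage_counts, stages_done, status = "ok")
  write_manifest_json(manifest, out("run_manifest.json"))
  outputs <- list.files(config$out_dir, full.names = TRUE)
  invisible(list(manifest = manifest, results = results, outputs = outputs))
}

build_manifest <- function(config, stage_counts, stages_done, status) {
  list(
    software = paste("ptiseq", as.character(utils::packageVersion("ptiseq"))),
    status = status,
    config = unclass(config),
    seed = config$seed,
    input_checksums = file_checksums(c(config$counts, config$sample_sheet,
                                       config$annotations, config$tf_annotations,
                                       config$genome, config$gff, config$motifs)),
    stage_row_counts = stage_counts,
    stages = stages_done,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

file_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  if (length(paths) == 0) return(list())
  sums <- vapply(paths, function(p) as.character(tools::md5sum(p)), character(1))
  as.list(setNames(sums, basename(paths)))
}

# Atomic JSON write: temp file in the same directory, then rename.
write_manifest_json <- function(manifest, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Simulates counts, genome, gene models, GO and TF-family annotations with
#' planted structure and writes them (plus the truth manifest) into a
#' directory, ready for [run_config()] / [run_pipeline()].
#'
#' @param out_dir Output directory.
#' @param n_genes Number of genes. Default 2000.
#' @param seed Master seed. Default 1.
#' @param design Optional [time_course_design()] overriding `n_genes`.
#' @param truth Optional [planted_truth()] overriding the default.
#' @return Named list of written file paths (plus `truth`, invisibly usable
#'   for recovery scoring).
#' @export
simulate_bundle <- function(out_dir, n_genes = 2000, seed = 1L,
                            design = NULL, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- design %||% time_course_design(n_genes = n_genes)
  truth <- truth %||% planted_truth(design, seed = seed)
  sim <- simulate_counts(design, truth)
  gen <- simulate_genome(truth)
  ann <- simulate_annotations(truth)
  # TF-family map: genes of the motif-bearing archetypes tagged with the
  # matching family at elevated rate, background elsewhere
  tf <- simulate_tf_families(truth)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    sample_sheet = file.path(out_dir, "samples.tsv"),
    genome = file.path(out_dir, "genome.fasta"),
    gff = file.path(out_dir, "genes.gff3"),
    annotations = file.path(out_dir, "go_annotations.tsv"),
    tf_annotations = file.path(out_dir, "tf_families.tsv"),
    motifs = file.path(out_dir, "motifs.tsv"),
    manifest = file.path(out_dir, "truth_manifest.json")
  )
  write_counts(sim$counts, sim$samples, paths$counts, paths$sample_sheet)
  write_genome_fasta(gen$genome, paths$genome)
  write_gff3(gen$models, paths$gff)
  write_tsv_na(ann$annotations, paths$annotations)
  write_tsv_na(tf, paths$tf_annotations)
  write_tsv_na(motif_dictionary(), paths$motifs)
  manifest <- truth_manifest(truth, design,
                             extra = list(planted_motifs = gen$manifest$planted,
                                          enriched_terms = ann$enriched))
  write_manifest(manifest, paths$manifest)
  paths$truth <- truth
  invisible(paths)
}

# Archetype-linked TF-family annotation: members of an archetype whose
# promoters carry a family's element are themselves enriched for that family.
simulate_tf_families <- function(truth, background_rate = 0.03,
                                 enriched_rate = 0.25) {
  fams <- unique(motif_dictionary()$tf_family)
  odds <- truth$motif_odds
  fam_of_motif <- setNames(motif_dictionary()$tf_family, motif_dictionary()$name)
  with_seed(derive_seed(truth$seed, "tf-families"), {
    rows <- purrr::map_dfr(seq_len(nrow(truth$genes)), function(g) {
      a <- truth$genes$archetype[g]
      enriched_fams <- if (a > 0 && a <= nrow(odds)) {
        unique(unname(fam_of_motif[names(which(odds[a, ] > 0))]))
      } else character()
      keep <- runif(length(fams)) <
        ifelse(fams %in% enriched_fams, enriched_rate, background_rate)
      if (!any(keep)) return(NULL)
      tibble(gene_id = truth$genes$gene_id[g], term_id = fams[keep])
    })
    rows
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted cluster structure.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Score cluster recovery against a truth manifest
#'
#' @param assignment Cluster assignment tibble (`gene_id`, `cluster`).
#' @param truth A [planted_truth()] (or its `genes` tibble).
#' @return Tibble: `n_scored` (genes present in both), `ari`.
#' @export
compare_to_truth <- function(assignment, truth) {
  genes <- if (inherits(truth, "pti_truth")) truth$genes else truth
  joined <- inner_join(assignment, genes[, c("gene_id", "archetype")],
                       by = "gene_id")
  tibble(n_scored = nrow(joined),
         ari = adjusted_rand_index(joined$cluster, joined$archetype))
}
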