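#' Simulate a genome with planted promoter motifs
#'
#' Builds random-base contigs tiled with non-overlapping gene models (random
#' strand), then plants cis-element occurrences into each gene's promoter
#' window with archetype-dependent probability: a gene of archetype a
#' receives motif m with probability `o / (1 + o)` where
#' `o = truth$motif_odds[a, m]` (`o = 0` never plants — background matches in
#' the random sequence still arise at their closed-form rate; `o = Inf`
#' always plants). Planted words are written on the gene's sense strand, so
#' minus-strand plants appear reverse-complemented in the contig and are only
#' recoverable through strand-aware promoter extraction. Every planted
#' occurrence (gene, motif, promoter-local position, word) is recorded in the
#' manifest.
#'
#' Genes are laid out deterministically with `promoter_length` spacing so
#' windows never overlap a neighboring gene body; an explicit
#' `contig_length` too short to host them is rejected.
#'
#' @param truth A [planted_truth()].
#' @param motifs Motif tibble (`name`, `consensus`, ...); default
#'   [motif_dictionary()].
#' @param promoter_length Promoter window length. Default 1000.
#' @param gene_length CDS length of every simulated gene. Default 300.
#' @param genes_per_contig Genes per contig. Default 500.
#' @param contig_length Optional explicit contig length; error if too short.
#' @return List: `genome` (named character vector), `models` (tibble as from
#'   [read_gene_models()]), `manifest` (a [truth_manifest()] whose `planted`
#'   component lists all planted motif occurrences).
#' @export
simulate_genome <- function(truth,
                            motifs = motif_dictionary(),
                            promoter_length = 1000,
                            gene_length = 300,
                            genes_per_contig = 500,
                            contig_length = NULL) {
  stopifnot(inherits(truth, "pti_truth"))
  n <- nrow(truth$genes)
  compiled <- compile_motif_set(motifs)
  motif_names <- vapply(compiled, `[[`, character(1), "name")
  odds <- truth$motif_odds
  slot <- promoter_length + gene_length + 50L
  n_contigs <- ceiling(n / genes_per_contig)
  need_len <- slot * min(n, genes_per_contig) + 50L
  if (!is.null(contig_length) && contig_length < need_len) {
    abort(sprintf("contig_length %d too short to host %d genes with %d bp spacing (need %d)",
                  contig_length, min(n, genes_per_contig), promoter_length, need_len))
  }
  clen <- contig_length %||% need_len

  with_seed(derive_seed(truth$seed, "genome"), {
    genome <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE), collapse = "")
    }, character(1))
    names(genome) <- sprintf("chr%02d", seq_len(n_contigs))

    contig_of <- names(genome)[(seq_len(n) - 1L) %/% genes_per_contig + 1L]
    within_idx <- (seq_len(n) - 1L) %% genes_per_contig
    slot_start <- within_idx * slot + 26L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cds_start <- ifelse(strand == "+", slot_start + promoter_length, slot_start)
    cds_end <- cds_start + gene_length - 1L
    models <- tibble(gene_id = truth$genes$gene_id, contig = contig_of,
                     strand = strand,
                     cds_start = as.integer(cds_start),
                     cds_end = as.integer(cds_end))

    # promoter window genomic interval per gene
    prom_start <- ifelse(strand == "+", cds_start - promoter_length, cds_end + 1L)
    prom_end <- ifelse(strand == "+", cds_start - 1L, cds_end + promoter_length)

    planted <- list()
    for (g in seq_len(n)) {
      a <- truth$genes$archetype[g]
      if (a == 0 || a > nrow(odds)) next
      occupied <- integer(0)
      for (mi in seq_along(compiled)) {
        o <- odds[a, motif_names[mi]]
        if (is.na(o) || o == 0) next
        p_plant <- if (is.infinite(o)) 1 else o / (1 + o)
        if (runif(1) > p_plant) next
        m <- compiled[[mi]]
        words <- motif_words(m)
        word <- words[sample.int(length(words), 1)]
        w <- m$width
        pos <- NA_integer_
        for (try in 1:50) {
          cand <- sample.int(promoter_length - w + 1L, 1)
          if (!any(abs(occupied - cand) < w + 2L)) { pos <- cand; break }
        }
        if (is.na(pos)) next
        occupied <- c(occupied, pos)
        # map promoter-local position -> genomic coordinates and strand context
        if (strand[g] == "+") {
          gs <- prom_start[g] + pos - 1L
          ins <- word
        } else {
          gs <- prom_end[g] - (pos + w - 1L) + 1L
          ins <- revcomp(word)
        }
        ctg <- contig_of[g]
        substr(genome[[ctg]], gs, gs + w - 1L) <- ins
        planted[[length(planted) + 1L]] <-
          tibble(gene_id = truth$genes$gene_id[g], motif = m$name,
                 position = pos, word = word)
      }
    }
    planted_tbl <- if (length(planted)) bind_rows(planted) else
      tibble(gene_id = character(), motif = character(),
             position = integer(), word = character())
    manifest <- truth_manifest(truth,
                               extra = list(planted = planted_tbl,
                                            promoter_length = promoter_length))
    list(genome = genome, models = models, manifest = manifest)
  })
}

#' Write contig sequences to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive, strand in column 7)
#' for the one-CDS-per-gene models used throughout the package.
#'
#' @param models Tibble with `gene_id`, `contig`, `strand`, `cds_start`,
#'   `cds_end`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    writeLines(c(
      sprintf("%s\tptiseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, g$cds_start, g$cds_end, g$strand, g$gene_id),
      sprintf("%s\tptiseq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$contig, g$cds_start, g$cds_end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tptiseq\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$contig, g$cds_start, g$cds_end, g$strand, g$gene_id, g$gene_id)
    ), con)
  }
  invisible(path)
}
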