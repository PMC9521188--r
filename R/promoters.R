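#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file (single- or multi-line records).
#' @return Named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/CDS features and reduces them to one record per gene:
#' the CDS extremes of the gene's transcript (the longest-CDS transcript when
#' several exist), i.e. the coordinates bracketing the translated region.
#' All coordinates are GFF3-style 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return Tibble: `gene_id`, `contig`, `strand` (`"+"`/`"-"`), `cds_start`,
#'   `cds_end` (1-based inclusive extremes of the chosen CDS).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0) abort("no CDS features found in the GFF3 file")
  parent <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  cds_tbl <- tibble(
    transcript_id = parent,
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  mrna <- gff[gff$type %in% c("mRNA", "transcript")]
  tx2gene <- setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], character(1)),
    as.character(mrna$ID)
  )
  cds_tbl$gene_id <- unname(tx2gene[cds_tbl$transcript_id])
  # CDS attached directly to a gene feature (no mRNA level)
  cds_tbl$gene_id[is.na(cds_tbl$gene_id)] <-
    cds_tbl$transcript_id[is.na(cds_tbl$gene_id)]
  cds_tbl$gene_id <- sub("^gene:", "", cds_tbl$gene_id)
  per_tx <- cds_tbl |>
    group_by(.data$gene_id, .data$transcript_id, .data$contig, .data$strand) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              cds_len = sum(.data$end - .data$start + 1L), .groups = "drop")
  per_tx |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$cds_len), .data$transcript_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("gene_id", "contig", "strand", "cds_start", "cds_end") |>
    arrange(.data$gene_id)
}

#' Extract promoter sequences upstream of translation starts
#'
#' For each gene, takes the window of `promoter_length` bases immediately 5'
#' of the start codon on the gene's sense strand: for a plus-strand gene with
#' CDS starting at position s, genomic interval `[s - L, s - 1]` read
#' forward; for a minus-strand gene with CDS ending at position e, interval
#' `[e + 1, e + L]` reverse-complemented. Windows running off a contig edge
#' are clipped and flagged `truncated`.
#'
#' @param models Gene-model tibble from [read_gene_models()] (columns
#'   `gene_id`, `contig`, `strand`, `cds_start`, `cds_end`).
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @param promoter_length Window length in bp. Default 1000.
#' @return Tibble: `gene_id`, `contig`, `start`, `end` (1-based inclusive
#'   genomic interval of the window), `strand`, `truncated`, `sequence`
#'   (sense-strand promoter, 5' to 3' towards the start codon).
#' @examples
#' genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
#' models <- tibble::tibble(gene_id = "g1", contig = "chr1", strand = "+",
#'                          cds_start = 1501, cds_end = 1800)
#' extract_promoters(models, genome, promoter_length = 100)
#' @export
extract_promoters <- function(models, genome, promoter_length = 1000) {
  stopifnot(promoter_length >= 1)
  missing_contig <- setdiff(unique(models$contig), names(genome))
  if (length(missing_contig)) {
    abort(sprintf("contig '%s' not present in the genome", missing_contig[1]))
  }
  rows <- purrr::pmap_dfr(
    models[, c("gene_id", "contig", "strand", "cds_start", "cds_end")],
    function(gene_id, contig, strand, cds_start, cds_end) {
      clen <- nchar(genome[[contig]])
      if (strand == "+") {
        start <- cds_start - promoter_length
        end <- cds_start - 1L
      } else if (strand == "-") {
        start <- cds_end + 1L
        end <- cds_end + promoter_length
      } else {
        warn(sprintf("gene %s has no usable strand; skipped", gene_id))
        return(NULL)
      }
      truncated <- start < 1 || end > clen
      start <- max(start, 1L)
      end <- min(end, clen)
      if (end < start) {
        seq <- ""
        truncated <- TRUE
      } else {
        seq <- substr(genome[[contig]], start, end)
        if (strand == "-") seq <- revcomp(seq)
      }
      tibble(gene_id = gene_id, contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, truncated = truncated, sequence = seq)
    })
  rows
}

#' Write promoters to FASTA
#'
#' Headers follow `gene_id|contig:start-end(strand)` with a `|truncated`
#' suffix for clipped windows.
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  headers <- sprintf("%s|%s:%d-%d(%s)%s", promoters$gene_id, promoters$contig,
                     promoters$start, promoters$end, promoters$strand,
                     ifelse(promoters$truncated, "|truncated", ""))
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write promoter intervals as BED6
#'
#' BED uses 0-based half-open coordinates; the conversion from the package's
#' 1-based inclusive intervals happens here and only here.
#'
#' @inheritParams write_promoters_fasta
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- data.frame(chrom = promoters$contig,
                    chromStart = promoters$start - 1L,
                    chromEnd = promoters$end,
                    name = promoters$gene_id,
                    score = 0L,
                    strand = promoters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
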