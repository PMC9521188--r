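#' The built-in cis-regulatory element dictionary
#'
#' The degenerate consensus elements classically scanned for in plant
#' promoters, grouped by the transcription-factor family that binds them:
#' GCC-box, DRE/CRT and DRE-like (AP2/ERF); the Myc-related element
#' (MYC/NAC); G-box, G-box-like, ABRE-like, ACTCAT-element and TGA-element
#' (bZIP); AtMyb1-4 (MYB; AtMyb1 and AtMyb2 are two named entries sharing one
#' consensus, carried verbatim); W-box (WRKY); and CG-1 (CAMTA).
#'
#' The W-box is stored as `TTGAC(C/T)` — the canonical TTGACY reading of the
#' shorthand "TTGAC/T"; edit the returned tibble (or supply your own motif
#' file) for the alternative `TTGA(C/T)` reading.
#'
#' @return Tibble with columns `name`, `tf_family`, `consensus`.
#' @examples
#' motif_dictionary()
#' @export
motif_dictionary <- function() {
  tibble::tribble(
    ~name,            ~tf_family, ~consensus,
    "GCC-box",        "AP2/ERF",  "AGCCGCC",
    "DRE/CRT",        "AP2/ERF",  "(A/G)CCGAC",
    "DRE-like",       "AP2/ERF",  "(A/G/T)(A/G)CCGACN(A/T)",
    "Myc-related",    "MYC/NAC",  "CACATG",
    "G-box",          "bZIP",     "CACGTG",
    "G-box-like",     "bZIP",     "CACGT(A/T)",
    "ABRE-like",      "bZIP",     "(C/G/T)ACGTG(G/T)(A/C)",
    "ACTCAT-element", "bZIP",     "ACTCAT",
    "TGA-element",    "bZIP",     "TGACG",
    "AtMyb1",         "MYB",      "(A/C)TCC(A/T)ACC",
    "AtMyb2",         "MYB",      "(A/C)TCC(A/T)ACC",
    "AtMyb3",         "MYB",      "TAACTAAC",
    "AtMyb4",         "MYB",      "A(A/C)C(A/T)A(A/C)C",
    "W-box",          "WRKY",     "TTGAC(C/T)",
    "CG-1",           "CAMTA",    "(A/C/G)CGCG(T/C/G)"
  )
}

#' Compile a degenerate consensus into a motif pattern
#'
#' Parses consensus strings over `A C G T N` with bracketed alternation
#' groups such as `(A/G)` into a positional allowed-set representation.
#' `N` allows any of the four bases. An `N` in a scanned *sequence* never
#' matches a non-N pattern position (and pattern `N` matches only real
#' bases, not sequence `N`).
#'
#' @param consensus Consensus string, e.g. `"(A/G)CCGAC"`.
#' @param name Motif name; defaults to the consensus.
#' @param tf_family Optional transcription-factor family label.
#' @return A `pti_motif`: list with `name`, `tf_family`, `consensus`,
#'   `sets` (list of allowed-base character vectors, one per position),
#'   `width`, and `regex` (a lookahead regex matching at every start).
#' @examples
#' m <- compile_motif("(A/G)CCGAC", name = "DRE/CRT")
#' m$width
#' m$sets[[1]]
#' @export
compile_motif <- function(consensus, name = consensus, tf_family = NA_character_) {
  if (!nzchar(consensus)) abort("consensus must be non-empty")
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars)) {
        abort(sprintf("unbalanced '(' at position %d in '%s'", i, consensus))
      }
      toks <- strsplit(paste(chars[(i + 1):(j - 1)], collapse = ""), "/", fixed = TRUE)[[1]]
      if (length(toks) == 0 || any(!toks %in% c("A", "C", "G", "T"))) {
        abort(sprintf("illegal alternation group at position %d in '%s'", i, consensus))
      }
      sets[[length(sets) + 1L]] <- unique(toks)
      i <- j + 1L
    } else if (ch %in% c("A", "C", "G", "T")) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "N") {
      sets[[length(sets) + 1L]] <- c("A", "C", "G", "T")
      i <- i + 1L
    } else if (ch == ")") {
      abort(sprintf("unbalanced ')' at position %d in '%s'", i, consensus))
    } else {
      abort(sprintf("illegal character '%s' at position %d in '%s'", ch, i, consensus))
    }
  }
  regex <- paste0("(?=", paste(vapply(sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = ""), ")")
  structure(list(name = name, tf_family = tf_family, consensus = consensus,
                 sets = sets, width = length(sets), regex = regex),
            class = "pti_motif")
}

#' @export
print.pti_motif <- function(x, ...) {
  cat(sprintf("<pti_motif> %s (%s): %s, width %d\n",
              x$name, x$tf_family, x$consensus, x$width))
  invisible(x)
}

#' Enumerate every word matched by a motif
#'
#' @param motif A [compile_motif()] pattern.
#' @return Character vector of all distinct matching w-mers (the alternation
#'   product of the positional allowed sets).
#' @export
motif_words <- function(motif) {
  stopifnot(inherits(motif, "pti_motif"))
  grid <- expand.grid(rev(motif$sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(motif$sets)), drop = FALSE], 1, paste, collapse = ""))
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector over `A C G T N` (case-insensitive).
#' @return Reverse complement of each element, uppercase.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan one sequence for a motif
#'
#' Reports every sliding-window start where each base falls in the motif's
#' allowed set. With `strand_mode = "both"` the reverse complement is also
#' scanned and hits are mapped back to coordinates on the given (sense)
#' sequence: a minus-strand hit at reported position p means the reverse
#' complement of `substr(seq, p, p + width - 1)` matches the motif.
#'
#' @param sequence A single DNA string (may contain `N`; `N` never matches).
#' @param motif A `pti_motif` (or a consensus string, compiled on the fly).
#' @param strand_mode `"both"` (default) or `"given"`.
#' @param .rc Optional precomputed reverse complement of `sequence` (an
#'   internal optimization for bulk scans).
#' @return Tibble of hits: `position` (1-based start on the given sequence),
#'   `strand` (`"+"`/`"-"`), `match` (the matching word as read on the hit
#'   strand). Zero rows when nothing matches.
#' @examples
#' scan_promoter("AAAGCCGCCTT", compile_motif("AGCCGCC", "GCC-box"))
#' @export
scan_promoter <- function(sequence, motif, strand_mode = c("both", "given"),
                          .rc = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(motif)) motif <- compile_motif(motif)
  stopifnot(inherits(motif, "pti_motif"), length(sequence) == 1L)
  seq_up <- toupper(sequence)
  w <- motif$width
  hits_fwd <- regex_starts(seq_up, motif$regex)
  out <- tibble(position = hits_fwd, strand = rep("+", length(hits_fwd)))
  if (strand_mode == "both") {
    rc <- .rc %||% revcomp(seq_up)
    hits_rev <- regex_starts(rc, motif$regex)
    if (length(hits_rev)) {
      # position i on the revcomp maps to sense start L - i - w + 2
      pos <- nchar(seq_up) - hits_rev - w + 2L
      out <- bind_rows(out, tibble(position = pos, strand = "-"))
    }
  }
  if (nrow(out) == 0) {
    return(tibble(position = integer(), strand = character(), match = character()))
  }
  out <- arrange(out, .data$position, .data$strand)
  out$match <- vapply(seq_len(nrow(out)), function(i) {
    s <- substr(seq_up, out$position[i], out$position[i] + w - 1L)
    if (out$strand[i] == "-") revcomp(s) else s
  }, character(1))
  out
}

# All (overlapping) match start positions of a lookahead regex.
regex_starts <- function(seq, regex) {
  if (!nzchar(seq)) return(integer())
  m <- gregexpr(regex, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Motif hits across a promoter set
#'
#' Runs [scan_promoter()] for every (gene, motif) pair and returns the hits
#' in long form.
#'
#' @param promoters Tibble with at least `gene_id` and `sequence` columns
#'   (e.g. from [extract_promoters()]).
#' @param motifs Tibble with `name` and `consensus` columns (and optionally
#'   `tf_family`), e.g. [motif_dictionary()]; or a list of `pti_motif`.
#' @param strand_mode `"both"` (default) or `"given"`.
#' @return Tibble: `gene_id`, `motif`, `tf_family`, `position`, `strand`,
#'   `match`.
#' @export
motif_hits <- function(promoters, motifs = motif_dictionary(),
                       strand_mode = c("both", "given")) {
  strand_mode <- match.arg(strand_mode)
  compiled <- compile_motif_set(motifs)
  seqs <- toupper(promoters$sequence)
  lens <- nchar(seqs)
  rcs <- if (strand_mode == "both") revcomp(seqs) else NULL
  # vectorized: one gregexpr pass per motif per strand over all promoters
  starts_of <- function(texts, regex) {
    lapply(gregexpr(regex, texts, perl = TRUE),
           function(m) if (m[1] == -1) integer() else as.integer(m))
  }
  out <- purrr::map_dfr(compiled, function(m) {
    w <- m$width
    fwd <- starts_of(seqs, m$regex)
    nf <- lengths(fwd)
    tab <- tibble(gene_id = rep(promoters$gene_id, nf),
                  position = unlist(fwd),
                  strand = rep("+", sum(nf)),
                  match = substr(rep(seqs, nf), unlist(fwd),
                                 unlist(fwd) + w - 1L))
    if (strand_mode == "both") {
      rev <- starts_of(rcs, m$regex)
      nr <- lengths(rev)
      if (sum(nr) > 0) {
        pos <- rep(lens, nr) - unlist(rev) - w + 2L
        tab <- bind_rows(tab, tibble(
          gene_id = rep(promoters$gene_id, nr),
          position = as.integer(pos),
          strand = rep("-", sum(nr)),
          match = substr(rep(rcs, nr), unlist(rev), unlist(rev) + w - 1L)))
      }
    }
    if (nrow(tab) == 0) return(NULL)
    dplyr::bind_cols(tibble(motif = rep(m$name, nrow(tab)),
                            tf_family = rep(m$tf_family, nrow(tab))),
                     tab)[, c("gene_id", "motif", "tf_family",
                              "position", "strand", "match")]
  })
  if (nrow(out) > 0) out <- arrange(out, .data$gene_id, .data$motif,
                                    .data$position, .data$strand)
  out
}

compile_motif_set <- function(motifs) {
  if (inherits(motifs, "pti_motif")) return(list(motifs))
  if (is.list(motifs) && !is.data.frame(motifs)) {
    stopifnot(all(vapply(motifs, inherits, logical(1), "pti_motif")))
    return(motifs)
  }
  stopifnot(is.data.frame(motifs), all(c("name", "consensus") %in% names(motifs)))
  fam <- if ("tf_family" %in% names(motifs)) motifs$tf_family else
    rep(NA_character_, nrow(motifs))
  purrr::pmap(list(motifs$consensus, motifs$name, fam), compile_motif)
}

#' Gene x motif presence table
#'
#' Collapses motif hits to presence/absence per gene (a promoter with five
#' W-boxes counts once).
#'
#' @inheritParams motif_hits
#' @param hits Optional precomputed [motif_hits()] table; when supplied,
#'   scanning is skipped.
#' @return Tibble with `gene_id` and one logical column per motif, covering
#'   every gene in `promoters` and every motif in `motifs` (all-`FALSE` rows
#'   and columns retained; zero motif columns for an empty dictionary).
#' @export
presence_table <- function(promoters, motifs = motif_dictionary(),
                           strand_mode = c("both", "given"), hits = NULL) {
  strand_mode <- match.arg(strand_mode)
  compiled <- compile_motif_set(motifs)
  motif_names <- vapply(compiled, `[[`, character(1), "name")
  out <- tibble(gene_id = promoters$gene_id)
  if (length(motif_names) == 0) return(out)
  if (is.null(hits)) hits <- motif_hits(promoters, motifs, strand_mode)
  for (mn in motif_names) {
    got <- unique(hits$gene_id[hits$motif == mn])
    out[[mn]] <- out$gene_id %in% got
  }
  out
}
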