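# Degenerate consensus compilation and promoter scanning.

test_that("consensus parsing builds the right positional sets", {
  m <- compile_motif("(A/G)CCGAC")
  expect_identical(m$width, 6L)
  expect_setequal(m$sets[[1]], c("A", "G"))
  expect_identical(nrow(scan_promoter("GCCGAC", m, "given")), 1L)
  expect_identical(nrow(scan_promoter("ACCGAC", m, "given")), 1L)
  expect_identical(nrow(scan_promoter("TCCGAC", m, "given")), 0L)

  n <- compile_motif("N")
  expect_identical(length(motif_words(n)), 4L)

  dre <- compile_motif("(A/G/T)(A/G)CCGACN(A/T)")
  expect_identical(dre$width, 9L)
  expect_identical(length(motif_words(dre)), 48L)
  expect_identical(length(unique(motif_words(dre))), 48L)

  expect_error(compile_motif("(A/G"), "unbalanced")
  expect_error(compile_motif("AC)G"), "unbalanced")
  expect_error(compile_motif("AXG"), "illegal character 'X' at position 2")
  expect_error(compile_motif("(A/B)C"), "alternation group")
  expect_error(compile_motif(""), "non-empty")
})

test_that("scanning finds hand-checked matches on both strands", {
  gcc <- compile_motif("AGCCGCC", "GCC-box")
  h <- scan_promoter("AAAGCCGCCTT", gcc)
  expect_identical(h$position, 3L)
  expect_identical(h$strand, "+")

  wbox <- compile_motif("TTGAC(C/T)", "W-box")
  expect_identical(nrow(scan_promoter("TTGACC", wbox, "given")), 1L)
  expect_identical(nrow(scan_promoter("TTGACA", wbox, "given")), 0L)
  # reverse-complement hit: GGTCAA revcomps to TTGACC
  expect_identical(scan_promoter("GGTCAA", wbox, "both")$strand, "-")
  expect_identical(nrow(scan_promoter("GGTCAA", wbox, "given")), 0L)

  # overlapping matches are all reported
  myc <- compile_motif("CACATG")
  expect_identical(scan_promoter("CACACATGCACATG", myc, "given")$position,
                   c(3L, 9L))
  # N in the sequence never matches
  expect_identical(nrow(scan_promoter("TTGNCC", wbox, "both")), 0L)
  # empty sequence
  expect_identical(nrow(scan_promoter("", wbox)), 0L)
})

test_that("scanner agrees with the enumeration oracle on random sequences", {
  motifs <- motif_dictionary()
  withr::with_seed(55, {
    for (i in 1:40) {
      seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = "")
      mi <- (i %% nrow(motifs)) + 1
      m <- compile_motif(motifs$consensus[mi], motifs$name[mi])
      for (mode in c("given", "both")) {
        got <- scan_promoter(seq, m, mode)
        want <- scan_oracle(seq, m, mode)
        expect_identical(got$position, as.integer(want$position))
        expect_identical(got$strand, want$strand)
      }
    }
  })
})

test_that("both-strand scanning is reverse-complement symmetric", {
  motifs <- lapply(seq_len(nrow(motif_dictionary())),
    function(i) compile_motif(motif_dictionary()$consensus[i],
                              motif_dictionary()$name[i]))
  withr::with_seed(66, {
    for (r in 1:10) {
      seq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                   collapse = "")
      rc <- revcomp(seq)
      expect_identical(revcomp(rc), seq)
      for (m in motifs[sample(seq_along(motifs), 4)]) {
        a <- scan_promoter(seq, m, "both")
        b <- scan_promoter(rc, m, "both")
        # positions mirror: start p (width w) <-> L - p - w + 2
        mirrored <- sort(nchar(seq) - b$position - m$width + 2L)
        expect_identical(sort(a$position), mirrored)
      }
    }
  })
})

test_that("presence tables deduplicate hits and keep empty columns", {
  proms <- tibble::tibble(gene_id = c("two_gcc", "none"),
                          sequence = c("AGCCGCCAAAGCCGCC", "TTTTTTTTTTTT"))
  dict <- motif_dictionary()[motif_dictionary()$name %in% c("GCC-box", "G-box"), ]
  pres <- presence_table(proms, dict)
  expect_identical(pres$`GCC-box`, c(TRUE, FALSE))
  expect_identical(pres$`G-box`, c(FALSE, FALSE))
  hits <- motif_hits(proms, dict)
  expect_identical(nrow(hits[hits$motif == "GCC-box" & hits$strand == "+", ]), 2L)
  # empty motif list -> gene_id column only
  empty <- presence_table(proms, motif_dictionary()[0, ])
  expect_identical(names(empty), "gene_id")
})

test_that("bulk scanning equals per-sequence scanning", {
  withr::with_seed(77, {
    proms <- tibble::tibble(
      gene_id = paste0("g", 1:15),
      sequence = vapply(1:15, function(i) {
        paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      }, character(1)))
  })
  hits <- motif_hits(proms, strand_mode = "both")
  for (i in c(2, 9)) {
    for (nm in c("W-box", "DRE-like", "CG-1")) {
      row <- motif_dictionary()[motif_dictionary()$name == nm, ]
      one <- scan_promoter(proms$sequence[i], compile_motif(row$consensus, nm))
      sub <- hits[hits$gene_id == proms$gene_id[i] & hits$motif == nm, ]
      expect_identical(sub$position, one$position)
      expect_identical(sub$match, one$match)
    }
  }
})

test_that("background presence frequency matches the closed-form rate", {
  withr::with_seed(88, {
    proms <- tibble::tibble(
      gene_id = paste0("g", 1:600),
      sequence = vapply(1:600, function(i) {
        paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
      }, character(1)))
  })
  dict <- motif_dictionary()[motif_dictionary()$name %in%
                               c("Myc-related", "GCC-box", "DRE/CRT"), ]
  pres <- presence_table(proms, dict)
  for (i in seq_len(nrow(dict))) {
    m <- compile_motif(dict$consensus[i], dict$name[i])
    q <- length(motif_words(m)) / 4^m$width
    p_hit <- 1 - (1 - q)^(2 * (500 - m$width + 1))
    obs <- mean(pres[[dict$name[i]]])
    tol <- 3 * sqrt(p_hit * (1 - p_hit) / 600) + 0.02
    expect_lt(abs(obs - p_hit), tol)
  }
})
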