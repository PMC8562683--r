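# Primary/readout probe design rules.

# The brute-force enumeration/selection oracle lives in helper-oracles.R.

runoff_transcript <- function() {
  tpl <- ivt_control_template()
  pos <- regexpr("TAATACGACTCACTATA", tpl, fixed = TRUE)
  substr(tpl, pos + 17, nchar(tpl))
}

test_that("candidate extraction enforces run, GC, and spacing rules", {
  # homopolymer rule: no candidate spans an AAAAA run
  cons <- paste0("AAAAA", "GCGTACGTAGCTAGCGATCGTACGATCGGC")
  got <- extract_candidates(cons)
  expect_true(all(!grepl("AAAAA", got$sequence)))
  # GC bound arithmetic on a 25-mer: 11 G/C (44%) out, 12 G/C (48%) in
  w44 <- paste0(strrep("GC", 5), "G", strrep("AT", 7))     # 11 GC / 25
  w48 <- paste0(strrep("GC", 6), strrep("AT", 6), "A")     # 12 GC / 25
  expect_equal(gc_percent(w44), 44)
  expect_equal(gc_percent(w48), 48)
  got44 <- extract_candidates(w44)
  got48 <- extract_candidates(w48)
  expect_equal(nrow(got44), 0)
  expect_equal(nrow(got48), 1)
  # ambiguous bases are dropped and counted
  gotn <- extract_candidates(paste0("N", w48))
  expect_gte(attr(gotn, "n_dropped_ambiguous"), 1)
})

test_that("selection matches a brute-force oracle on the control transcript", {
  cons <- runoff_transcript()
  got <- extract_candidates(cons, gene = "ivt")
  oracle <- oracle_candidates(cons)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, oracle$start)
  expect_equal(got$sequence, oracle$seq)
  # spacing invariant: at least 2 nt between adjacent footprints
  if (nrow(got) > 1) {
    expect_true(all(got$start[-1] - got$end[-nrow(got)] >= 2))
  }
})

test_that("cross-hybridization drops the later probe at the 17-nt boundary", {
  block17 <- "ACGTACGTACGGATCCA"          # 17 nt
  p1 <- paste0(block17, "TGCATGCA")        # 25 nt
  p2 <- paste0("TTGACCAG", block17)        # shares exactly 17 nt
  probes <- tibble::tibble(gene = c("g1", "g2"), start = c(0, 0),
                           end = c(25, 25), sequence = c(p1, p2),
                           gc_percent = gc_percent(c(p1, p2)))
  kept <- cross_hyb_filter(probes)
  expect_equal(kept$gene, "g1")
  expect_equal(attr(kept, "dropped")$gene, "g2")
  # a 16-nt shared block is tolerated
  block16 <- substr(block17, 1, 16)
  q1 <- paste0(block16, "TTGCATGCA")
  q2 <- paste0("TTGACCAGA", block16)
  probes16 <- tibble::tibble(gene = c("g1", "g2"), start = 0, end = 25,
                             sequence = c(q1, q2),
                             gc_percent = gc_percent(c(q1, q2)))
  expect_equal(nrow(cross_hyb_filter(probes16)), 2)
  # reverse-strand matches count too
  r2 <- paste0("TTGACCAG", revcomp(block17))
  probes_rc <- tibble::tibble(gene = c("g1", "g2"), start = 0, end = 25,
                              sequence = c(p1, r2),
                              gc_percent = gc_percent(c(p1, r2)))
  expect_equal(nrow(cross_hyb_filter(probes_rc)), 1)
})

test_that("planted collisions are exactly the ones removed", {
  set.seed(12)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  c1 <- extract_candidates(rand_seq(320), gene = "g1")
  c2 <- extract_candidates(rand_seq(320), gene = "g2")
  # plant a duplicated 20-nt block across the two toy genes
  block <- substr(c1$sequence[2], 3, 22)
  c2$sequence[3] <- paste0(substr(c2$sequence[3], 1, 2), block,
                           substr(c2$sequence[3], 23, nchar(c2$sequence[3])))
  pool <- dplyr::bind_rows(c1, c2)
  kept <- cross_hyb_filter(pool)
  expect_true(nrow(attr(kept, "dropped")) >= 1)
  # brute-force all-pairs oracle over the original pool
  shares17 <- function(a, b) {
    for (i in 1:(nchar(a) - 16)) {
      k <- substr(a, i, i + 16)
      if (grepl(k, b, fixed = TRUE) || grepl(k, revcomp(b), fixed = TRUE)) {
        return(TRUE)
      }
    }
    FALSE
  }
  n <- nrow(pool)
  collide <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    collide[i, j] <- collide[j, i] <- shares17(pool$sequence[i],
                                               pool$sequence[j])
  }
  # sequential oracle mirroring the deterministic later-drop rule
  keep <- logical(n)
  for (i in 1:n) keep[i] <- !any(collide[i, seq_len(i - 1)] & keep[seq_len(i - 1)])
  expect_equal(paste(kept$gene, kept$start),
               paste(pool$gene[keep], pool$start[keep]))
  # the kept set is collision-free by the all-pairs check
  expect_true(all(!collide[keep, keep]))
})

test_that("oversized sets are trimmed toward 55% GC with the stated tie-break", {
  small <- tibble::tibble(gene = "g", start = 0:19 * 30, end = 0:19 * 30 + 25,
                          sequence = strrep("A", 25),
                          gc_percent = seq(45, 64, 1))
  expect_identical(trim_set(small), small)  # <= 32 unchanged
  set.seed(2)
  gcs <- sample(seq(40, 74, length.out = 35))
  big <- tibble::tibble(gene = "g", start = 0:34 * 30, end = 0:34 * 30 + 25,
                        sequence = strrep("A", 25), gc_percent = gcs)
  trimmed <- trim_set(big, max_size = 32)
  keep_oracle <- sort(order(abs(gcs - 55))[1:32])  # sort-and-keep oracle
  expect_equal(nrow(trimmed), 32)
  expect_setequal(trimmed$gc_percent, gcs[keep_oracle])
  # tie-break: of two probes equidistant from 55, the later start goes
  tie <- tibble::tibble(gene = "g", start = c(0, 100, 200),
                        end = c(25, 125, 225), sequence = strrep("A", 25),
                        gc_percent = c(50, 60, 55))
  t1 <- trim_set(tie, max_size = 2)
  expect_equal(t1$start, c(0, 200))
})

test_that("readouts with 15-nt or longer transcriptome matches are dropped", {
  set.seed(6)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  ref <- rand_seq(600)
  readouts <- vapply(1:12, function(i) rand_seq(20), character(1))
  # plant 16-nt reference overlaps into 3 readouts
  for (i in c(2, 7, 11)) {
    piece <- substr(ref, 100 + i * 10, 115 + i * 10)  # 16 nt from reference
    readouts[i] <- paste0(substr(readouts[i], 1, 4), piece)
  }
  kept <- filter_readouts(readouts, ref)
  expect_equal(which(!attr(kept, "kept")), c(2, 7, 11))
  # boundary: an exact 15-nt match disqualifies, 14 nt does not
  r15 <- paste0(substr(ref, 1, 15), rand_seq(5))
  r14 <- paste0(substr(ref, 301, 314), rand_seq(6))
  k <- filter_readouts(c(r15, r14), ref)
  expect_equal(attr(k, "kept"), c(FALSE, TRUE))
})

test_that("primary oligos are target + TA + reverse-complement readout", {
  probes <- tibble::tibble(gene = "g", start = 0, end = 25,
                           sequence = "ACGTACGTACGTACGTACGTACGTA",
                           gc_percent = 48)
  readout <- "TTACGGATCCAGTCAGTCAG"
  oligo <- assemble_primary_probes(probes, readout)
  expect_equal(nchar(oligo$oligo), 25 + 2 + 20)
  expect_equal(substr(oligo$oligo, 26, 27), "TA")
  expect_equal(substr(oligo$oligo, 28, 47), revcomp(readout))
  expect_equal(oligo$target_sequence, revcomp(probes$sequence))
  expect_equal(revcomp(revcomp(readout)), readout)
  expect_equal(oligo$oligo,
               paste0(oligo$target_sequence, "TA", revcomp(readout)))
})

test_that("the full design is sound, idempotent, and byte-deterministic", {
  set.seed(99)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  consensus <- c(geneA = rand_seq(900), geneB = rand_seq(800))
  readouts <- vapply(1:4, function(i) rand_seq(20), character(1))
  design <- design_probes(consensus, readouts)
  # soundness: re-verify every emitted probe against all rules
  sense <- tibble::tibble(gene = design$probes$gene,
                          start = design$probes$start,
                          end = design$probes$end,
                          sequence = revcomp(design$probes$target_sequence))
  violations <- verify_probe_set(sense)
  expect_equal(nrow(violations), 0)
  # idempotence: the selected windows re-run through the rule chain unchanged
  again <- trim_set(cross_hyb_filter(sense |>
                                       dplyr::mutate(gc_percent = gc_percent(sequence))))
  expect_equal(again$start, design$probes$start)
  expect_equal(again$gene, design$probes$gene)
  # determinism: byte-identical FASTA on repeat runs
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_probes_fasta(design, f1)
  write_probes_fasta(design_probes(consensus, readouts), f2)
  expect_identical(readLines(f1), readLines(f2))
  # design report tracks per-gene sizes and flags
  expect_equal(design$report$gene, c("geneA", "geneB"))
  expect_true(all(design$report$n_final <= 32))
})
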