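# m6A level arithmetic, seqFISH decoding, normalization, embedding, QC.

test_that("single-cell m6A level is the modified fraction", {
  expect_equal(round(100 * cell_m6a_level(0.51e6, 0.14e6)), 27)
  expect_equal(cell_m6a_level(100, 0), 0)
  expect_equal(cell_m6a_level(100, 100), 1)
  expect_true(is.na(cell_m6a_level(0, 0)))
  expect_error(cell_m6a_level(10, 11), "exceeds")
  expect_error(cell_m6a_level(-1, 0), ">= 0")
})

test_that("gene m6A levels apply the dual reliability filter", {
  expect_true(is.na(gene_m6a_level(9, 2, 0.01)))       # both filters fail
  expect_equal(gene_m6a_level(10, 5, -1), 0.5)          # count filter passes
  expect_equal(gene_m6a_level(3, 1, 0.02), 1 / 3)       # expression filter
  expect_true(is.na(gene_m6a_level(0, 0, 0.5)))         # zero total undefined
  # vectorized, NA exactly when both filters fail
  tot <- c(9, 10, 200, 5); lme <- c(0.01, -0.5, 0.5, 0.03)
  got <- gene_m6a_level(tot, c(1, 5, 100, 2), lme)
  expect_equal(is.na(got), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("gene m6A estimates converge to planted fractions", {
  set.seed(77)
  for (f in c(0.1, 0.5, 0.9)) {
    total <- 200
    mods <- rbinom(50, total, f)
    est <- gene_m6a_level(rep(total, 50), mods, rep(1, 50))
    se <- sqrt(f * (1 - f) / total)
    expect_lt(abs(mean(est) - f), 3 * se / sqrt(50) + 3 * se)
    expect_true(all(est >= 0 & est <= 1))
  }
})

make_round_spots <- function(counts_by_gene_cell, cell_info, genes) {
  # synthesize aligned spot tables with the requested per-(gene, cell) counts
  rows <- list()
  for (k in seq_len(nrow(cell_info))) {
    for (g in seq_along(genes)) {
      n <- counts_by_gene_cell[g, k]
      if (n == 0) next
      ctr <- random_centers(n, c(64, 64), min_sep = 3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fov_row = cell_info$fov_row[k], fov_col = cell_info$fov_col[k],
        round = g, row = ctr$row, col = ctr$col)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("seqFISH decoding recovers planted per-gene counts exactly", {
  set.seed(19)
  genes <- c("GAPDH", "ENO1", "EEF2", "HBG1")
  map <- tibble::tibble(round = 1:4, gene = genes)
  cell_info <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                              fov_row = 1:3, fov_col = 1)
  planted <- matrix(c(5, 0, 7,
                      2, 3, 0,
                      0, 0, 0,
                      8, 1, 4), 4, 3, byrow = TRUE)
  spots <- make_round_spots(planted, cell_info, genes)
  expr <- decode_seqfish(spots, map, cell_info)
  expect_equal(unname(expr$counts), planted)
  expect_equal(rownames(expr$counts), genes)
  # blank round -> zero row for that gene
  expect_true(all(expr$counts["EEF2", ] == 0))
  # unmapped round errors
  bad <- spots; bad$round[1] <- 9
  expect_error(decode_seqfish(bad, map, cell_info), "no gene assignment")
  # coupling to an m6A map counts colocalized spots per gene
  m6a_map <- spots[spots$round == 1 & spots$fov_row == 1, ][1:3, ]
  m6a_map <- m6a_map[, c("fov_row", "fov_col", "row", "col")]
  expr2 <- decode_seqfish(spots, map, cell_info, m6a_spots = m6a_map)
  expect_equal(unname(expr2$modified[, 1]), c(3, 0, 0, 0))
  expect_true(all(expr2$modified <= expr2$counts))
})

test_that("normalization divides, logs, and centers gene rows", {
  counts <- matrix(c(4, 8, 2, 2), 2, 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expr <- structure(list(
    counts = counts, modified = counts * NA,
    cells = tibble::tibble(cell_id = c("c1", "c2"), total_count = c(16, 16)),
    genes = c("g1", "g2")), class = "m6a_expression")
  norm <- normalize_expression(expr, pseudocount = 1 / 16)
  # hand-evaluated: log2(4/16 + 1/16) = log2(5/16), log2(9/16), log2(3/16)
  g1 <- c(log2(5 / 16), log2(9 / 16)); g2 <- c(log2(3 / 16), log2(3 / 16))
  expect_equal(unname(norm$values[1, ]), g1 - mean(g1))
  expect_equal(unname(norm$values[2, ]), g2 - mean(g2))
  expect_equal(unname(norm$log_mean_expr), c(mean(g1), mean(g2)))
  # gene rows are mean-centered
  expect_true(all(abs(rowMeans(norm$values)) < 1e-9))
  # identical cells normalize to all zeros
  same <- expr; same$counts <- matrix(c(4, 4, 2, 2), 2, 2, byrow = TRUE,
                                      dimnames = dimnames(counts))
  expect_true(all(normalize_expression(same)$values == 0))
  # ratio invariance: doubling counts and totals changes nothing
  dbl <- expr
  dbl$counts <- counts * 2
  dbl$cells$total_count <- c(32, 32)
  expect_equal(normalize_expression(dbl, pseudocount = 1 / 16)$values,
               norm$values)
  # zero-total cells are excluded with a warning
  z <- expr; z$cells$total_count <- c(16, 0)
  expect_warning(nz <- normalize_expression(z), "zero total")
  expect_equal(ncol(nz$values), 1)
})

test_that("t-SNE embeds cells deterministically and separates planted clusters", {
  set.seed(4)
  n_per <- 25; n_genes <- 9
  a <- matrix(rnorm(n_genes * n_per, 0), n_genes, n_per)
  b <- matrix(rnorm(n_genes * n_per, 4), n_genes, n_per)
  values <- cbind(a, b)
  colnames(values) <- sprintf("c%02d", seq_len(2 * n_per))
  norm <- structure(list(
    values = values - rowMeans(values), log_mean_expr = rowMeans(values),
    cells = tibble::tibble(cell_id = colnames(values),
                           phenotype = rep(c("A", "B"), each = n_per))),
    class = "m6a_normalized")
  emb <- embed_cells(norm, perplexity = 10, seed = 5)
  expect_equal(dim(emb[, c("tsne1", "tsne2")]), c(50, 2))
  emb2 <- embed_cells(norm, perplexity = 10, seed = 5)
  expect_identical(emb$tsne1, emb2$tsne1)
  # silhouette of the true labels in the embedding
  sil <- function(e, labels) {
    xy <- cbind(e$tsne1, e$tsne2)
    d <- as.matrix(dist(xy))
    s <- vapply(seq_len(nrow(xy)), function(i) {
      own <- labels == labels[i]; own[i] <- FALSE
      a_i <- mean(d[i, own]); b_i <- mean(d[i, !own])
      (b_i - a_i) / max(a_i, b_i)
    }, numeric(1))
    mean(s)
  }
  expect_gt(sil(emb, norm$cells$phenotype), 0.3)
  # too few cells for the perplexity -> actionable error
  tiny <- norm
  tiny$values <- norm$values[, 1:12]; tiny$cells <- norm$cells[1:12, ]
  expect_error(embed_cells(tiny, perplexity = 10), "perplexity")
})

test_that("housekeeping QC flags cells with undetected controls", {
  counts <- matrix(1, 4, 3,
                   dimnames = list(c("GAPDH", "ENO1", "EEF2", "MYC"),
                                   c("c1", "c2", "c3")))
  counts[1:3, 2] <- 0      # all housekeeping genes absent in c2
  counts[1:2, 3] <- 0      # one housekeeping gene left in c3
  expr <- structure(list(counts = counts, modified = counts * NA,
                         cells = tibble::tibble(cell_id = colnames(counts)),
                         genes = rownames(counts)),
                    class = "m6a_expression")
  qc <- qc_cells(expr, min_detect = 1)
  expect_equal(qc$qc_pass, c(TRUE, FALSE, TRUE))
  qc3 <- qc_cells(expr, min_detect = 3)
  expect_equal(qc3$qc_pass, c(TRUE, FALSE, FALSE))
  expect_error(qc_cells(expr, housekeeping = c("GAPDH", "ACTB")), "ACTB")
})

test_that("planted low-quality cells are flagged by QC", {
  set.seed(31)
  n <- 60
  counts <- matrix(rpois(9 * n, 5), 9, n,
                   dimnames = list(c("GAPDH", "ENO1", "EEF2", paste0("g", 1:6)),
                                   sprintf("c%02d", 1:n)))
  low <- sample(n, 6)  # 10% low-quality: housekeeping dropout
  counts[1:3, low] <- 0
  expr <- structure(list(counts = counts, modified = counts * NA,
                         cells = tibble::tibble(cell_id = colnames(counts)),
                         genes = rownames(counts)),
                    class = "m6a_expression")
  qc <- qc_cells(expr, min_detect = 1)
  expect_gte(mean(!qc$qc_pass[low]), 0.9)
  expect_true(all(qc$qc_pass[-low]))
})
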