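# Nanowell scan analysis, COM/RDM construction, matrix registration, linking.

test_that("cell detection finds planted cells at their wells", {
  blank <- list(nuclear = matrix(0, 80, 80), ch1 = matrix(0, 80, 80),
                ch2 = matrix(0, 80, 80))
  expect_equal(nrow(detect_cells(blank, well_pitch = 8, threshold = 10)), 0)
  expect_error(detect_cells(list(ch1 = matrix(0, 8, 8)), 8), "nuclear")

  set.seed(14)
  cells <- tibble::tibble(
    well_row = sample(1:10, 20, replace = TRUE),
    well_col = sample(1:10, 20, replace = TRUE),
    phenotype = "K562", ch1 = 800, ch2 = 100)
  cells <- dplyr::distinct(cells, well_row, well_col, .keep_all = TRUE)
  scan <- simulate_nanowell_scan(cells, grid = c(10, 10), well_pitch = 10,
                                 noise = noiseless(), seed = 3)
  det <- detect_cells(scan$images, well_pitch = 10, threshold = 50)
  expect_equal(nrow(det), nrow(cells))
  expect_setequal(paste(det$well_row, det$well_col),
                  paste(cells$well_row, cells$well_col))
})

test_that("two cells in one well yield two records sharing the well index", {
  # render two resolvable nuclei inside well (5, 5) of a 12-px grid
  blobs <- tibble::tibble(row = c(51, 55.5), col = c(51, 55.5),
                          amplitude = 1000)
  nuc <- render_clean(blobs, shape = c(120, 120), psf_sigma = 1.5)
  scan <- list(nuclear = nuc, ch1 = nuc, ch2 = nuc * 0)
  det <- detect_cells(scan, well_pitch = 12, threshold = 50, min_sep = 2)
  shared <- det[det$well_row == 5 & det$well_col == 5, ]
  expect_equal(nrow(shared), 2)
})

test_that("phenotype gating labels cells and rejects overlapping gates", {
  gates <- default_gates()
  cells <- tibble::tibble(row = 0, col = 0, nuclear = 1,
                          ch1 = c(900, 120, 400 - 1e-9), ch2 = c(100, 900, 0),
                          well_row = 1:3, well_col = 1)
  lab <- classify_phenotype(cells, gates)
  expect_equal(lab$phenotype[1:2], c("K562", "YAC1"))
  expect_true(lab$ch1[3] < 400 || is.na(lab$phenotype[3]))
  out <- classify_phenotype(dplyr::mutate(cells, ch1 = -5), gates)
  expect_true(all(is.na(out$phenotype)))
  bad <- tibble::tibble(phenotype = c("A", "B"), channel = "ch1",
                        min = c(0, 50), max = c(100, 150))
  expect_error(classify_phenotype(cells, bad), "overlap")
})

test_that("simulated mixtures are gated with at least 99% accuracy", {
  cfg <- small_sim_config(seqfish_rounds = 0)
  sim <- simulate_experiment(cfg, seed = 17, render_images = FALSE)
  det <- detect_cells(sim$scan$images, well_pitch = cfg$well_pitch)
  det <- classify_phenotype(det, default_gates())
  truth <- sim$ground_truth$cells
  # judge gating on singlet wells; doublet wells mix stain intensities
  singlets <- dplyr::filter(dplyr::count(truth, well_row, well_col), n == 1)
  truth1 <- dplyr::semi_join(truth, singlets, by = c("well_row", "well_col"))
  joined <- dplyr::inner_join(
    det, truth1[, c("well_row", "well_col", "phenotype")],
    by = c("well_row", "well_col"), suffix = c("_called", "_true"))
  acc <- mean(joined$phenotype_called == joined$phenotype_true, na.rm = TRUE)
  expect_gte(acc, 0.99)
})

test_that("occupancy matrices count cells per well", {
  empty <- build_com(tibble::tibble(well_row = integer(),
                                    well_col = integer()), shape = c(5, 7))
  expect_true(all(empty == 0))
  two <- build_com(tibble::tibble(well_row = c(2, 2), well_col = c(3, 3)),
                   shape = c(5, 7))
  expect_equal(two[2, 3], 2L)
  expect_equal(sum(two), 2L)
  expect_warning(build_com(tibble::tibble(well_row = 9, well_col = 1),
                           shape = c(5, 7)), "outside")
  # round trip: planted cells at least two well pitches apart recover exactly
  set.seed(29)
  lattice <- expand.grid(well_row = seq(1, 19, 2), well_col = seq(1, 29, 2))
  pick <- lattice[sample(nrow(lattice), 100), ]
  cells <- tibble::tibble(well_row = pick$well_row, well_col = pick$well_col,
                          phenotype = "K562", ch1 = 800, ch2 = 100)
  scan <- simulate_nanowell_scan(cells, grid = c(20, 30), well_pitch = 10,
                                 noise = noiseless(), seed = 5)
  det <- detect_cells(scan$images, well_pitch = 10, threshold = 50)
  expect_equal(nrow(det), 100)
  com <- build_com(det, shape = c(20, 30))
  expect_equal(com, build_com(cells, shape = c(20, 30)))
})

test_that("density matrices respect the modified <= total invariant", {
  counts <- tibble::tibble(fov_row = c(1, 2), fov_col = c(1, 2),
                           total_count = c(10, 0), m6a_count = c(3, 0))
  rdm <- build_rdm(counts, shape = c(3, 4))
  expect_equal(rdm$total[1, 1], 10)
  expect_equal(rdm$modified[1, 1], 3)
  expect_true(is.na(rdm$total[3, 4]))  # missing FOV flagged
  expect_true(all(rdm$modified <= rdm$total, na.rm = TRUE))
  expect_error(build_rdm(tibble::tibble(fov_row = 1, fov_col = 1,
                                        total_count = 2, m6a_count = 5),
                         shape = c(3, 4)), "exceeds")
  grid <- expand.grid(fov_row = 1:3, fov_col = 1:4)
  blank <- build_rdm(tibble::tibble(fov_row = grid$fov_row,
                                    fov_col = grid$fov_col,
                                    total_count = 0, m6a_count = 0),
                     shape = c(3, 4))
  expect_true(all(blank$total == 0))
})

test_that("a planted pattern is recovered at its exact offset", {
  set.seed(41)
  com <- matrix(rpois(121 * 381, 0.3), 121, 381)
  patt <- matrix(rbinom(31 * 51, 1, 0.4) * 3, 31, 51)
  com[41:71, 121:171] <- patt
  reg <- register_rdm_to_com(patt, com)
  expect_equal(unname(reg$offset), c(40, 120))
  expect_true(reg$valid)
  expect_equal(max(reg$map, na.rm = TRUE), reg$correlation)
  # map covers every translation
  expect_equal(dim(reg$map), c(121 - 31 + 1, 381 - 51 + 1))
  # top-left subset recovers offset (0, 0)
  com2 <- matrix(0, 40, 60); com2[1:10, 1:15] <- matrix(rpois(150, 2), 10, 15)
  reg2 <- register_rdm_to_com(com2[1:10, 1:15], com2)
  expect_equal(unname(reg2$offset), c(0, 0))
})

test_that("fft and direct correlation maps agree and registration is equivariant", {
  set.seed(42)
  com <- matrix(rpois(30 * 40, 1), 30, 40)
  rdm <- matrix(rpois(6 * 8, 1), 6, 8)
  f <- register_rdm_to_com(rdm, com, method = "fft")
  d <- register_rdm_to_com(rdm, com, method = "direct")
  expect_equal(f$map, d$map, tolerance = 1e-10)
  # equivariance: shifting the planted pattern shifts the recovered offset
  base <- matrix(rpois(50 * 70, 0.5), 50, 70)
  patt <- matrix(rbinom(8 * 10, 1, 0.5) * 4, 8, 10)
  for (sh in list(c(0, 0), c(7, 11), c(30, 42))) {
    com_s <- base
    com_s[(1:8) + sh[1], (1:10) + sh[2]] <- patt
    reg <- register_rdm_to_com(patt, com_s)
    expect_equal(unname(reg$offset), sh)
  }
})

test_that("missing FOVs are excluded pairwise and constant inputs error", {
  set.seed(43)
  com <- matrix(rpois(30 * 40, 1), 30, 40)
  patt <- matrix(rpois(6 * 8, 3), 6, 8)
  com[11:16, 21:28] <- patt
  rdm <- patt; rdm[2, 3] <- NA; rdm[5, 1] <- NA
  reg <- register_rdm_to_com(rdm, com)
  expect_equal(unname(reg$offset), c(10, 20))
  expect_error(register_rdm_to_com(matrix(1, 4, 4), matrix(1, 10, 10)),
               "constant|undefined")
  expect_error(register_rdm_to_com(matrix(1, 12, 12), matrix(1, 10, 14)),
               "strictly smaller")
})

test_that("registration recovery is reliable across random occupancy draws", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    com <- matrix(rpois(60 * 90, 0.3), 60, 90)
    patt <- matrix(rpois(12 * 18, 0.5), 12, 18)
    off <- c(sample(0:(60 - 12), 1), sample(0:(90 - 18), 1))
    com[(1:12) + off[1], (1:18) + off[2]] <- patt
    reg <- register_rdm_to_com(patt, com)
    identical(unname(reg$offset), off)
  }, logical(1))
  expect_true(all(hits))
})

test_that("only singlet wells are linked, with their planted phenotypes", {
  # construct a known COM/RDM pair: 10 singlets, 3 doublets, rest empty
  com <- matrix(0L, 12, 16)
  singlets <- cbind(2:11, 3:12); doublets <- cbind(2:4, 14)
  com[singlets] <- 1L; com[doublets] <- 2L
  rdm_counts <- tibble::tibble(
    fov_row = rep(1:6, each = 8), fov_col = rep(1:8, 6),
    total_count = 50, m6a_count = 10)
  rdm <- build_rdm(rdm_counts, shape = c(6, 8))
  # registered window at offset (1, 2): wells rows 2..7, cols 3..10
  reg <- structure(list(offset = c(row = 1L, col = 2L), correlation = 1,
                        map = matrix(0, 7, 9), zscore = 10, valid = TRUE,
                        z_threshold = 5), class = "m6a_registration")
  cells <- tibble::tibble(
    well_row = c(singlets[, 1], doublets[, 1], doublets[, 1]),
    well_col = c(singlets[, 2], doublets[, 2], doublets[, 2]),
    ch1 = 800, ch2 = 100,
    phenotype = "K562")
  linked <- link_single_cells(reg, com, cells, rdm)
  in_window <- singlets[, 1] >= 2 & singlets[, 1] <= 7 &
    singlets[, 2] >= 3 & singlets[, 2] <= 10
  expect_equal(nrow(linked), sum(in_window))
  expect_true(all(linked$phenotype == "K562"))
  expect_true(all(linked$m6a_level == 0.2))
  # empty wells only -> zero records
  linked0 <- link_single_cells(reg, matrix(0L, 12, 16), cells, rdm)
  expect_equal(nrow(linked0), 0)
  # invalid registration refuses to link
  bad <- reg; bad$valid <- FALSE
  expect_error(link_single_cells(bad, com, cells, rdm), "refus")
})
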