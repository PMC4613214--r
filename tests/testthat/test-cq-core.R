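test_that("long-format round trip preserves the dataset, including NAs", {
  for (seed in 1:5) {
    set.seed(seed)
    ds <- random_ds(n_genes = 3, n_samples = 4, seed = seed)
    ds$cq[sample(nrow(ds), 2)] <- NA          # plates have failed wells
    ds <- cq_dataset(ds)
    path <- withr::local_tempfile(fileext = ".csv")
    write_table(ds, path)
    back <- read_cq_table(path, layout = "long")
    expect_equal(dplyr::arrange(tibble::as_tibble(back), gene, sample),
                 dplyr::arrange(tibble::as_tibble(ds), gene, sample))
  }
})

test_that("wide layout with sidecar annotations matches the long layout", {
  m <- matrix(c(20.5, 21, 22, 23.25, 24, 25), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  ds <- ds_from_matrix(m, condition = c("t0", "t0", "t1"),
                       bio_rep = c(1L, 2L, 1L))
  wide <- withr::local_tempfile(fileext = ".csv")
  ann <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(cbind(gene = rownames(m),
                                           as.data.frame(m))), wide)
  readr::write_csv(tibble::tibble(sample = colnames(m), tissue = "leaf",
                                  condition = c("t0", "t0", "t1"),
                                  bio_rep = c(1L, 2L, 1L)), ann)
  back <- read_cq_table(wide, layout = "wide", annotations = ann)
  expect_equal(dplyr::arrange(tibble::as_tibble(back), gene, sample),
               dplyr::arrange(tibble::as_tibble(ds), gene, sample))
})

test_that("malformed tables fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # missing column
  readr::write_csv(tibble::tibble(gene = "a", sample = "s", cq = 20), path)
  expect_error(read_cq_table(path), "tissue")
  # non-numeric Cq reported with its row number
  tbl <- tibble::tibble(gene = rep(c("a", "b"), each = 4),
                        sample = rep(paste0("s", 1:4), 2),
                        tissue = "leaf", condition = "c1",
                        bio_rep = 1L, cq = as.character(20:27))
  tbl$cq[7] <- "abc"
  readr::write_csv(tbl, path)
  expect_error(read_cq_table(path), "row 7")
  # duplicate (gene, sample)
  tbl$cq[7] <- "26"
  tbl$sample[2] <- "s1"
  readr::write_csv(tbl, path)
  expect_error(read_cq_table(path), "duplicate")
  # NA cells become missing, others intact
  tbl$sample[2] <- "s2"
  tbl$cq[3] <- "NA"
  readr::write_csv(tbl, path)
  ds <- read_cq_table(path)
  expect_true(is.na(ds$cq[ds$gene == "a" & ds$sample == "s3"]))
  expect_equal(sum(is.na(ds$cq)), 1)
})

test_that("Cq validation enforces the measurement range and keys", {
  base <- tibble::tibble(gene = rep(c("a", "b"), 2),
                         sample = rep(c("s1", "s2"), each = 2),
                         tissue = "leaf", condition = "c1", bio_rep = 1L,
                         cq = c(20, 21, 22, 23))
  expect_s3_class(cq_dataset(base), "cq_data")
  bad <- base; bad$cq[1] <- 47
  expect_error(cq_dataset(bad), "\\(0, 45\\)")
  bad <- base; bad$cq[1] <- -1
  expect_error(cq_dataset(bad), "\\(0, 45\\)")
  expect_error(cq_dataset(base[base$gene == "a", ]), "at least 2 genes")
})

test_that("technical replicates average arithmetically and keep NA groups", {
  tbl <- tibble::tibble(
    gene = rep(c("a", "b"), each = 6),
    sample = paste0(rep(c("a", "b"), each = 6), rep(1:6, 2)),
    tissue = "leaf",
    condition = rep(rep(c("t0", "t1"), each = 3), 2),
    bio_rep = 1L,
    tech_rep = rep(1:3, 4),
    cq = c(20.0, 20.2, 20.4,  20.0, NA, 21.0,
           25, 25, 25,        NA, NA, NA))
  out <- average_technical_replicates(cq_dataset(tbl))
  expect_false(has_tech_reps(out))
  a <- out$cq[out$gene == "a"]
  expect_equal(sort(a), c(20.2, 20.5))
  expect_true(is.na(out$cq[out$gene == "b" & out$condition == "t1"]))
  expect_equal(out$cq[out$gene == "b" & out$condition == "t0"], 25)
})

test_that("quantity transform halves per cycle and anchors the max at 1", {
  m <- rbind(g1 = c(20, 21, 22), g2 = c(25, 25, 25))
  ds <- ds_from_matrix(m)
  eff <- efficiency_table(c(g1 = 2, g2 = 2))
  q <- to_quantities(ds, eff)
  expect_equal(unname(unclass(q)["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(unclass(q)["g2", ]), c(1, 1, 1))
  # non-integer efficiency
  m2 <- rbind(g1 = c(20, 21), g2 = c(20, 20))
  q2 <- to_quantities(ds_from_matrix(m2), efficiency_table(c(g1 = 1.9, g2 = 2)))
  expect_equal(unname(unclass(q2)["g1", 2]), 1 / 1.9, tolerance = 1e-12)
})

test_that("quantities satisfy the normalization and monotonicity invariants", {
  for (seed in 1:5) {
    ds <- random_ds(n_genes = 5, n_samples = 7, seed = seed)
    q <- to_quantities(ds, random_eff(sort(unique(ds$gene)), seed))
    expect_true(all(unclass(q) > 0 & unclass(q) <= 1))
    expect_equal(unname(apply(unclass(q), 1, max)), rep(1, 5))
    # lower Cq => strictly higher quantity, within each gene
    mat <- refstab:::.cq_matrix(ds)$cq
    for (g in rownames(mat)) {
      ord <- order(mat[g, ])
      expect_true(all(diff(unclass(q)[g, ord]) < 0 |
                        diff(mat[g, ord]) == 0))
    }
  }
  expect_error(to_quantities(
    ds_from_matrix(rbind(g1 = c(NA_real_, NA_real_), g2 = c(20, 21)))),
    "g1")
})

test_that("gene summaries work on condition means and shift correctly", {
  m <- rbind(g1 = c(24.0, 24.5, 25.0), g2 = c(26, 26, 26))
  ds <- ds_from_matrix(m, condition = c("t0", "t1", "t2"))
  s <- summarize_cq(ds)
  expect_equal(s$range_cq[s$gene == "g1"], 1.0)
  expect_equal(s$range_cq[s$gene == "g2"], 0)
  expect_equal(s$sd_cq[s$gene == "g2"], 0)
  expect_true(all(s$min_cq <= s$mean_cq & s$mean_cq <= s$max_cq))
  # translation equivariance: +c cycles shifts the mean, not spread
  ds2 <- ds
  ds2$cq[ds2$gene == "g1"] <- ds2$cq[ds2$gene == "g1"] + 3
  s2 <- summarize_cq(cq_dataset(ds2))
  expect_equal(s2$range_cq, s$range_cq)
  expect_equal(s2$sd_cq, s$sd_cq)
  expect_equal(s2$mean_cq[s2$gene == "g1"], s$mean_cq[s$gene == "g1"] + 3)
})

test_that("efficiency tables validate range and default to doubling", {
  expect_error(efficiency_table(c(a = 0.9)), "> 1")
  expect_warning(efficiency_table(c(a = 2.5, b = 2)), "typical")
  eff <- efficiency_table(c(g1 = 1.9))
  expect_warning(e <- refstab:::.eff_vector(eff, c("g1", "g2")), "E = 2")
  expect_equal(unname(e), c(1.9, 2.0))
})

test_that("ranking tables are written sorted by rank", {
  ds <- random_ds(seed = 3)
  r <- as_ranking(pairwise_dct(ds))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(r, path, header_lines = "demo")
  back <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_equal(back$rank, sort(back$rank))
  expect_error(suppressWarnings(
    write_table(r, file.path(tempdir(), "no/such/dir/x.csv"))),
    "cannot open")
})
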