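test_that("control calibration sets the control geometric mean to 1", {
  m <- rbind(g1 = c(25, 25, 24, 26), g2 = c(22, 23, 22.4, 21))
  ds <- ds_from_matrix(m, condition = c("t0", "t0", "t1", "t1"),
                       bio_rep = c(1L, 2L, 1L, 2L))
  eff <- efficiency_table(c(g1 = 2, g2 = 1.9))
  q <- graynorm_quantities(ds, eff, "t0")
  ctrl <- attr(q, "sample_info")$condition == "t0"
  for (g in rownames(q)) {
    expect_equal(exp(mean(log(unclass(q)[g, ctrl]))), 1, tolerance = 1e-12)
  }
  # one cycle earlier than the control mean doubles the quantity (E = 2)
  expect_equal(unname(unclass(q)["g1", 3]), 2, tolerance = 1e-12)
  # one cycle later with E = 1.9 gives 1/1.9
  m2 <- rbind(g1 = c(25, 26), g2 = c(22, 22))
  ds2 <- ds_from_matrix(m2, condition = c("t0", "t1"))
  q2 <- graynorm_quantities(ds2, efficiency_table(c(g1 = 1.9, g2 = 2)), "t0")
  expect_equal(unname(unclass(q2)["g1", 2]), 1 / 1.9, tolerance = 1e-12)
  expect_error(graynorm_quantities(ds, eff, "t9"), "not present")
  m3 <- rbind(g1 = c(NA, NA, 24, 26), g2 = c(22, 23, 22.4, 21))
  expect_error(graynorm_quantities(
    ds_from_matrix(m3, condition = c("t0", "t0", "t1", "t1"),
                   bio_rep = c(1L, 2L, 1L, 2L)), eff, "t0"), "g1")
})

test_that("combination scores capture deviation of condition-averaged 1/NF", {
  # perfectly stable genes: every condition mean is 1
  m <- rbind(g1 = rep(24, 6), g2 = rep(26, 6))
  ds <- ds_from_matrix(m, condition = rep(c("t0", "t1", "t2"), each = 2),
                       bio_rep = rep(1:2, 3))
  eff <- efficiency_table(c(g1 = 2, g2 = 2))
  sc <- graynorm_score(ds, eff, c("g1", "g2"), "t0")
  expect_equal(sc$cumulative_deviation, 0, tolerance = 1e-12)
  expect_equal(sc$cv_inter, 0, tolerance = 1e-12)
  expect_equal(sc$condition_means$mean_inv_nf, rep(1, 3), tolerance = 1e-12)

  # single gene +1 cycle in exactly one treated condition: 1/NF = 2 there
  m2 <- rbind(g1 = c(24, 24, 24, 24, 25, 24), g2 = rep(26, 6))
  ds2 <- ds_from_matrix(m2, condition = paste0("t", 0:5),
                        bio_rep = rep(1L, 6))
  sc2 <- graynorm_score(ds2, eff, "g1", "t0")
  expect_equal(sc2$condition_means$mean_inv_nf[
    sc2$condition_means$condition == "t4"], 2, tolerance = 1e-12)
  expect_equal(sc2$cumulative_deviation, 1.0, tolerance = 1e-12)

  # opposite one-cycle shifts cancel in the two-gene geometric mean
  m3 <- rbind(g1 = c(24, 25), g2 = c(26, 25))
  ds3 <- ds_from_matrix(m3, condition = c("t0", "t1"))
  sc3 <- graynorm_score(ds3, eff, c("g1", "g2"), "t0")
  expect_equal(sc3$cumulative_deviation, 0, tolerance = 1e-12)
  expect_error(graynorm_score(ds3, eff, "nope", "t0"), "nope")
  expect_error(graynorm_score(ds3, eff, character(), "t0"), "non-empty")
})

test_that("scores match an independent loop-based oracle on random data", {
  for (seed in 1:15) {
    ds <- random_ds(n_genes = 4, n_samples = 6, seed = seed)
    eff <- random_eff(paste0("g", 1:4), seed)
    e <- stats::setNames(eff$efficiency, eff$gene)
    mat <- refstab:::.cq_matrix(ds)
    set.seed(seed + 500)
    combo <- sample(paste0("g", 1:4), sample(2:4, 1))
    sc <- graynorm_score(ds, eff, combo, "c1")
    exp_sc <- oracle_graynorm(mat$cq, e, mat$info$condition, "c1", combo)
    expect_equal(sc$cumulative_deviation, exp_sc$cumulative_deviation,
                 tolerance = 1e-12)
    expect_equal(sc$cv_inter, exp_sc$cv_inter, tolerance = 1e-12)
  }
})

test_that("exhaustive enumeration covers 2^G - 1 combinations and is consistent", {
  ds <- random_ds(n_genes = 5, n_samples = 6, seed = 21)
  eff <- random_eff(paste0("g", 1:5), 21)
  ranked <- graynorm_rank_all(ds, eff, "c1")
  expect_equal(nrow(ranked), 2^5 - 1)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # best combination equals the minimum found by independent re-scoring
  e <- stats::setNames(eff$efficiency, eff$gene)
  mat <- refstab:::.cq_matrix(ds)
  best_dev <- Inf; best_combo <- NULL
  for (s in 1:5) {
    for (i in seq_len(ncol(utils::combn(5, s)))) {
      combo <- paste0("g", utils::combn(5, s)[, i])
      dev <- oracle_graynorm(mat$cq, e, mat$info$condition, "c1",
                             combo)$cumulative_deviation
      if (dev < best_dev) { best_dev <- dev; best_combo <- combo }
    }
  }
  expect_equal(ranked$cumulative_deviation[1], best_dev, tolerance = 1e-12)
  expect_equal(ranked$combination[1], paste(sort(best_combo), collapse = ";"))
  # per-combination scores agree with graynorm_score throughout
  idx <- c(1, 7, nrow(ranked))
  for (i in idx) {
    combo <- strsplit(ranked$combination[i], ";")[[1]]
    expect_equal(graynorm_score(ds, eff, combo, "c1")$cumulative_deviation,
                 ranked$cumulative_deviation[i], tolerance = 1e-12)
  }
})

test_that("adding a condition-responsive gene degrades a stable combination", {
  m <- rbind(g1 = rep(24, 4), g2 = rep(25, 4), bad = c(24, 24, 26, 26))
  ds <- ds_from_matrix(m, condition = c("t0", "t0", "t1", "t1"),
                       bio_rep = c(1L, 2L, 1L, 2L))
  eff <- efficiency_table(c(g1 = 2, g2 = 2, bad = 2))
  stable <- graynorm_score(ds, eff, c("g1", "g2"), "t0")$cumulative_deviation
  spoiled <- graynorm_score(ds, eff, c("g1", "g2", "bad"),
                            "t0")$cumulative_deviation
  expect_gte(spoiled, stable)
  ranked <- graynorm_rank_all(ds, eff, "t0")
  expect_false(grepl("bad", ranked$combination[1]))
})

test_that("combination selection honours the minimum-size rule", {
  ds <- random_ds(n_genes = 4, n_samples = 6, seed = 33)
  eff <- random_eff(paste0("g", 1:4), 33)
  ranked <- graynorm_rank_all(ds, eff, "c1")
  sel <- select_combination(ranked, min_genes = 3)
  expect_gte(length(sel), 3)
  first3 <- ranked[ranked$size >= 3, ]
  expect_equal(paste(sort(as.character(sel)), collapse = ";"),
               first3$combination[1])
  sel1 <- select_combination(ranked, min_genes = 1)
  expect_equal(paste(sort(as.character(sel1)), collapse = ";"),
               ranked$combination[1])
  expect_error(select_combination(ranked, min_genes = 9), "at least 9")
  expect_error(graynorm_rank_all(ds, eff, "c1", max_genes = 3), "guard")
})

test_that("per-gene GrayNorm ranking orders singletons by deviation", {
  ds <- random_ds(n_genes = 4, n_samples = 6, seed = 40)
  eff <- random_eff(paste0("g", 1:4), 40)
  ranked <- graynorm_rank_all(ds, eff, "c1")
  r <- graynorm_gene_ranking(ranked)
  expect_equal(nrow(r), 4)
  singles <- ranked[ranked$size == 1, ]
  expect_equal(r$gene[1], singles$combination[which.min(
    singles$cumulative_deviation)])
})
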