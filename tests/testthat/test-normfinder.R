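# Step-by-step re-implementation of the variance decomposition, written as
# plain loops, to check the vectorized kernel.
oracle_normfinder <- function(q, grp) {
  y <- log2(q)
  G <- nrow(y)
  z <- y
  for (s in seq_len(ncol(y))) z[, s] <- y[, s] - mean(y[, s])
  ks <- sort(unique(grp))
  zbar <- s2 <- matrix(0, G, length(ks))
  n_k <- integer(length(ks))
  for (ki in seq_along(ks)) {
    cols <- which(grp == ks[ki])
    n_k[ki] <- length(cols)
    for (g in seq_len(G)) {
      zbar[g, ki] <- mean(z[g, cols])
      s2[g, ki] <- var(z[g, cols])
    }
  }
  sigma2 <- matrix(0, G, length(ks))
  for (ki in seq_along(ks)) {
    for (g in seq_len(G)) {
      sigma2[g, ki] <- max(0, s2[g, ki] * (1 - 2 / G) +
                             sum(s2[, ki]) / (G * (G - 1)))
    }
  }
  if (length(ks) == 1) return(stats::setNames(sqrt(sigma2[, 1]), rownames(y)))
  stab <- numeric(G)
  for (g in seq_len(G)) {
    d <- zbar[g, ] - mean(zbar[g, ])
    v <- sigma2[g, ] / n_k
    gamma2 <- max(0, var(d) - mean(v))
    dt <- d * gamma2 / (gamma2 + v)
    dt[!is.finite(dt)] <- 0
    stab[g] <- mean(abs(dt) + sqrt(v))
  }
  stats::setNames(stab, rownames(y))
}

test_that("constant genes have zero stability value", {
  m <- rbind(g1 = rep(24, 6), g2 = rep(26, 6), g3 = rep(22, 6))
  res <- suppressWarnings(
    normfinder_stability(ds_from_matrix(m, condition = rep(c("c1", "c2"), 3),
                                        bio_rep = rep(1:3, each = 2)),
                         groups = "condition"))
  expect_equal(res$ranking$score, rep(0, 3))
})

test_that("a noisy gene ranks last with a single group", {
  set.seed(4)
  m <- rbind(A = rep(24, 8), B = rep(25, 8), C = 26 + rnorm(8, 0, 1))
  res <- suppressWarnings(
    normfinder_stability(ds_from_matrix(m, condition = rep("c1", 8),
                                        bio_rep = 1:8),
                         groups = "condition"))
  expect_equal(res$ranking$gene[res$ranking$rank == 3], "C")
})

test_that("the decomposition matches a step-by-step oracle", {
  for (seed in 1:20) {
    ds <- random_ds(n_genes = 5, n_samples = 8, seed = seed,
                    conditions = rep(c("c1", "c2"), each = 4))
    eff <- random_eff(paste0("g", 1:5), seed)
    res <- normfinder_stability(ds, eff, groups = "condition")
    q <- unclass(to_quantities(ds, eff))
    info <- attr(to_quantities(ds, eff), "sample_info")
    expected <- oracle_normfinder(q[, info$sample], info$condition)
    got <- stats::setNames(res$ranking$score, res$ranking$gene)
    expect_equal(got[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("stability is invariant to per-gene scaling and relabeling", {
  ds <- random_ds(n_genes = 4, n_samples = 8, seed = 5,
                  conditions = rep(c("c1", "c2"), each = 4))
  eff <- random_eff(paste0("g", 1:4), 5)
  res <- normfinder_stability(ds, eff, groups = "condition")
  # adding a constant to one gene's Cq rescales its quantities; the
  # sample-centering and group-mean-centering make stability blind to it
  ds2 <- ds
  ds2$cq[ds2$gene == "g2"] <- ds2$cq[ds2$gene == "g2"] + 2
  res2 <- normfinder_stability(cq_dataset(ds2), eff, groups = "condition")
  expect_equal(res2$ranking, res$ranking, tolerance = 1e-9)
  # permuting samples within groups changes nothing
  ds3 <- ds
  swap <- c(s1 = "s3", s3 = "s1")
  ds3$sample <- ifelse(ds3$sample %in% names(swap), swap[ds3$sample],
                       ds3$sample)
  res3 <- normfinder_stability(cq_dataset(ds3), eff, groups = "condition")
  expect_equal(res3$ranking$score, res$ranking$score, tolerance = 1e-9)
})

test_that("a group-shifted gene is detected as least stable", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    G <- 4; S <- 8
    m <- matrix(rnorm(G * S, 0, 0.05), G, S) + c(22, 24, 26, 28)
    m[4, 5:8] <- m[4, 5:8] + 1          # +1 cycle in group 2 only
    rownames(m) <- paste0("g", 1:G)
    ds <- ds_from_matrix(m, condition = rep(c("c1", "c2"), each = 4),
                         bio_rep = rep(1:4, 2))
    res <- suppressWarnings(normfinder_stability(ds, groups = "condition"))
    hits <- hits + (res$ranking$gene[res$ranking$rank == G] == "g4")
  }
  expect_gte(hits, 95)
})

test_that("preconditions on group sizes and gene counts are enforced", {
  m <- rbind(g1 = 20:23, g2 = 21:24, g3 = 22:25)
  ds <- ds_from_matrix(m, condition = c("c1", "c1", "c1", "c2"))
  expect_error(suppressWarnings(normfinder_stability(ds, groups = "condition")),
               "at least 2")
  expect_error(suppressWarnings(normfinder_stability(
    ds_from_matrix(m[1:2, ], condition = rep("c1", 4)))), "at least 3 genes")
})

test_that("the best pair exploits intergroup cancellation", {
  # genes A and B respond in opposite directions across groups; their
  # average is flatter than either alone
  m <- rbind(A = c(24, 24, 25, 25), B = c(26, 26, 25, 25),
             C = c(22, 22, 22, 22), D = c(23, 23.1, 22.9, 23))
  ds <- ds_from_matrix(m, condition = rep(c("c1", "c2"), each = 2),
                       bio_rep = rep(1:2, 2))
  eff <- efficiency_table(stats::setNames(rep(2, 4), c("A", "B", "C", "D")))
  res <- normfinder_stability(ds, eff, groups = "condition")
  pair <- normfinder_best_pair(res)
  expect_true(all(sort(pair$genes) %in% c("A", "B", "C", "D")))
  ab <- pair$candidates
  ab_score <- ab$stability[ab$gene_1 == "A" & ab$gene_2 == "B"]
  # the opposed pair scores better than pairing either gene with itself
  # would suggest from the singleton ranking
  a_single <- res$ranking$score[res$ranking$gene == "A"]
  expect_lt(ab_score, a_single)
  # single-group input refuses pair search
  ds1 <- ds_from_matrix(m, condition = rep("c1", 4), bio_rep = 1:4)
  res1 <- normfinder_stability(ds1, eff, groups = "condition")
  expect_error(normfinder_best_pair(res1), "2 groups")
})

test_that("identical genes tie and the first pair is reported", {
  m <- rbind(A = c(22, 23, 22, 23), B = c(22, 23, 22, 23),
             C = c(22, 23, 22, 23))
  ds <- ds_from_matrix(m, condition = rep(c("c1", "c2"), 2),
                       bio_rep = c(1, 1, 2, 2))
  res <- suppressWarnings(normfinder_stability(ds, groups = "condition"))
  pair <- normfinder_best_pair(res)
  expect_equal(pair$genes, c("A", "B"))
})
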