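# Builders for small in-code fixtures and independent brute-force oracles.
# The oracles deliberately use plain loops / prod() / sd() so they share no
# code path with the package kernels they check.

ds_from_matrix <- function(m, tissue = "leaf", condition = NULL,
                           bio_rep = NULL) {
  genes <- rownames(m)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  samples <- colnames(m)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  if (is.null(condition)) condition <- paste0("c", seq_len(ncol(m)))
  if (is.null(bio_rep)) bio_rep <- rep(1L, ncol(m))
  cq_dataset(tibble::tibble(
    gene = rep(genes, each = ncol(m)),
    sample = rep(samples, nrow(m)),
    tissue = tissue,
    condition = rep(condition, nrow(m)),
    bio_rep = rep(bio_rep, nrow(m)),
    cq = as.vector(t(m))))
}

random_ds <- function(n_genes = 4, n_samples = 6, seed = 1,
                      conditions = NULL) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples, 20, 30), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (is.null(conditions)) {
    conditions <- rep(paste0("c", seq_len(ceiling(n_samples / 2))),
                      each = 2)[seq_len(n_samples)]
  }
  ds_from_matrix(m, condition = conditions,
                 bio_rep = as.integer(stats::ave(seq_len(n_samples),
                                                 conditions,
                                                 FUN = seq_along)))
}

random_eff <- function(genes, seed = 1) {
  set.seed(seed)
  efficiency_table(tibble::tibble(gene = genes,
                                  efficiency = runif(length(genes), 1.85, 2.1)))
}

# --- oracles -----------------------------------------------------------

oracle_msd <- function(m) {
  G <- nrow(m)
  msd <- numeric(G)
  for (i in seq_len(G)) {
    sds <- c()
    for (j in seq_len(G)) {
      if (i == j) next
      d <- m[i, ] - m[j, ]
      d <- d[!is.na(d)]
      sds <- c(sds, sd(d))
    }
    msd[i] <- mean(sds)
  }
  names(msd) <- rownames(m)
  msd
}

oracle_genorm_m <- function(q) {
  G <- nrow(q)
  m_val <- numeric(G)
  for (j in seq_len(G)) {
    vs <- c()
    for (k in seq_len(G)) {
      if (j == k) next
      vs <- c(vs, sd(log2(q[j, ] / q[k, ])))
    }
    m_val[j] <- mean(vs)
  }
  names(m_val) <- rownames(q)
  m_val
}

# GrayNorm score from raw pieces: cq matrix, named efficiencies, per-sample
# condition labels; geometric condition averages of 1/NF.
oracle_graynorm <- function(cq, e, condition, control, combination) {
  ctrl_cols <- which(condition == control)
  inv_nf <- numeric(ncol(cq))
  for (s in seq_len(ncol(cq))) {
    qs <- numeric(length(combination))
    for (gi in seq_along(combination)) {
      g <- combination[gi]
      qs[gi] <- e[g] ^ (mean(cq[g, ctrl_cols]) - cq[g, s])
    }
    inv_nf[s] <- 1 / prod(qs) ^ (1 / length(qs))
  }
  m <- c()
  for (cond in sort(unique(condition))) {
    m[cond] <- prod(inv_nf[condition == cond]) ^
      (1 / sum(condition == cond))
  }
  list(condition_means = m,
       cv_inter = 100 * sd(m) / mean(m),
       cumulative_deviation = sum(abs(m[names(m) != control] - 1)))
}

oracle_pairwise_variation <- function(q, ranked) {
  geo <- function(x) prod(x) ^ (1 / length(x))
  v <- c()
  for (n in 2:(length(ranked) - 1)) {
    nf_n <- apply(q[ranked[1:n], , drop = FALSE], 2, geo)
    nf_n1 <- apply(q[ranked[1:(n + 1)], , drop = FALSE], 2, geo)
    v <- c(v, sd(log2(nf_n / nf_n1)))
  }
  v
}

oracle_footrule <- function(a, b) {
  tot <- 0
  for (item in a) {
    tot <- tot + abs(which(a == item) - which(b == item))
  }
  tot
}
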