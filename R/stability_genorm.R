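#' geNorm expression-stability measure M
#'
#' For each gene j, M_j is the mean over all other genes k of the standard
#' deviation (n-1) across samples of the log2 expression ratio
#' `A_jk = log2(q_j / q_k)`. A constant ratio (stable or co-regulated pair)
#' contributes 0; low M marks stable expression.
#'
#' @param q A `quantity_matrix` from [to_quantities()], or any strictly
#'   positive genes x samples matrix.
#' @return Named numeric vector of M values, one per gene.
#' @export
genorm_m <- function(q) {
  q <- .as_quantity(q)
  G <- nrow(q)
  if (G < 2) stop("genorm_m: need at least 2 genes", call. = FALSE)
  lq <- log2(q)
  v <- matrix(0, G, G, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(G - 1)) {
    for (k in (j + 1):G) {
      v[j, k] <- v[k, j] <- stats::sd(lq[j, ] - lq[k, ])
    }
  }
  rowSums(v) / (G - 1)
}

.as_quantity <- function(q) {
  m <- unclass(q)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a genes x samples quantity matrix", call. = FALSE)
  }
  if (anyNA(m) || any(m <= 0)) {
    stop("quantities must be strictly positive and complete", call. = FALSE)
  }
  m
}

#' geNorm ranking by iterative exclusion
#'
#' Repeatedly computes M on the remaining gene set and excludes the gene
#' with the highest M (ties: the lexicographically last gene, recorded),
#' until two genes remain. The final pair cannot be resolved by M (their
#' mutual ratio SD is identical) and shares rank 1. Each gene's reported M
#' is its value at the step it was excluded.
#'
#' @param q A `quantity_matrix` (at least 3 genes).
#' @return An object of class `genorm_result`: list with
#'   \describe{
#'     \item{ranking}{tibble `gene, m_value, rank` (final pair rank 1).}
#'     \item{exclusion_order}{Genes from first excluded (least stable) to
#'       the final pair.}
#'     \item{initial_m}{M values in the full starting set (used to order
#'       the final pair when a full permutation is required).}
#'     \item{ties}{Character vector describing tie-breaks applied.}
#'   }
#' @export
genorm_rank <- function(q) {
  q <- .as_quantity(q)
  if (nrow(q) < 3) stop("genorm_rank: need at least 3 genes", call. = FALSE)
  initial_m <- genorm_m(q)
  remaining <- rownames(q)
  excluded <- character()
  m_at_exclusion <- numeric()
  ties <- character()
  while (length(remaining) > 2) {
    m <- genorm_m(q[remaining, , drop = FALSE])
    worst_m <- max(m)
    cand <- names(m)[m == worst_m]
    worst <- cand[order(cand)][length(cand)]    # lexicographically last
    if (length(cand) > 1) {
      ties <- c(ties, paste0("tie at M=", signif(worst_m, 6), " among ",
                             paste(sort(cand), collapse = ","),
                             "; excluded ", worst))
    }
    excluded <- c(excluded, worst)
    m_at_exclusion <- c(m_at_exclusion, worst_m)
    remaining <- setdiff(remaining, worst)
  }
  final_m <- genorm_m(q[remaining, , drop = FALSE])
  genes <- c(excluded, sort(remaining))
  m_val <- c(m_at_exclusion, unname(final_m[sort(remaining)]))
  rank <- c(seq(length(excluded) + 2, 3), 1L, 1L)  # first excluded = rank G
  ord <- order(rank, genes)
  ranking <- tibble::tibble(gene = genes[ord], m_value = m_val[ord],
                            rank = rank[ord])
  out <- list(ranking = ranking,
              exclusion_order = excluded,
              final_pair = sort(remaining),
              initial_m = initial_m,
              ties = ties)
  class(out) <- "genorm_result"
  out
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result> geNorm iterative-exclusion ranking\n")
  print(x$ranking)
  invisible(x)
}

#' @export
as_ranking.genorm_result <- function(x, ...) {
  # Full permutation: final pair ordered by initial (full-set) M value.
  pair <- x$final_pair[order(x$initial_m[x$final_pair], x$final_pair)]
  genes <- c(pair, rev(x$exclusion_order))
  score <- x$ranking$m_value[match(genes, x$ranking$gene)]
  out <- tibble::tibble(gene = genes, score = score,
                        rank = seq_along(genes),
                        tied = genes %in% x$final_pair,
                        method = "genorm")
  class(out) <- c("stability_ranking", class(tibble::tibble()))
  out
}

#' Normalization factor of a reference-gene set
#'
#' The per-sample geometric mean of the chosen genes' relative quantities.
#'
#' @param q A `quantity_matrix` (or positive matrix).
#' @param gene_set Non-empty character vector of genes present in `q`.
#' @return An object of class `normalization_factor`: tibble
#'   `sample, nf` with attribute `genes`.
#' @export
normalization_factor <- function(q, gene_set) {
  q <- .as_quantity(q)
  if (length(gene_set) == 0) {
    stop("normalization_factor: gene_set must be non-empty", call. = FALSE)
  }
  missing_genes <- setdiff(gene_set, rownames(q))
  if (length(missing_genes) > 0) {
    stop("normalization_factor: gene(s) not in quantity matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  nf <- exp(colMeans(log(q[gene_set, , drop = FALSE])))
  out <- tibble::tibble(sample = colnames(q), nf = unname(nf))
  attr(out, "genes") <- sort(gene_set)
  class(out) <- c("normalization_factor", class(out))
  out
}

#' Pairwise variation series V(n/n+1)
#'
#' Measures the effect of adding the (n+1)-th ranked gene to the
#' normalization factor: `V_n/n+1 = SD over samples of
#' log2(NF_n / NF_n+1)`, where NF_n uses the top n genes of the supplied
#' ranking. A small V means the extra gene hardly changes normalization.
#'
#' @param q A `quantity_matrix`.
#' @param ranked_genes Genes ordered best to worst, length >= 3.
#' @return Tibble of class `pv_series` with columns `n`, `v`
#'   (n = 2 .. length-1).
#' @export
pairwise_variation <- function(q, ranked_genes) {
  q <- .as_quantity(q)
  if (length(ranked_genes) < 3) {
    stop("pairwise_variation: need at least 3 ranked genes", call. = FALSE)
  }
  ns <- 2:(length(ranked_genes) - 1)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(q, ranked_genes[seq_len(n)])$nf
    nf_n1 <- normalization_factor(q, ranked_genes[seq_len(n + 1)])$nf
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  out <- tibble::tibble(n = ns, v = v)
  class(out) <- c("pv_series", class(out))
  out
}

#' How many reference genes are enough?
#'
#' Applies the standard V(n/n+1) decision rule: use the smallest n whose
#' V(n/n+1) falls below `threshold` (default 0.15), but never fewer than
#' `min_genes` (default 3, guarding against co-regulated pairs). If no V
#' drops below the threshold, use n+1 genes at the minimum of the series.
#'
#' @param series A [pairwise_variation()] result.
#' @param threshold V cut-off, default 0.15.
#' @param min_genes Floor on the recommendation, default 3.
#' @return List with `n` (recommended gene count) and `rule` (one of
#'   `"threshold"`, `"minimum-genes floor"`, `"minimum of V"`).
#' @export
recommend_count <- function(series, threshold = 0.15, min_genes = 3) {
  stopifnot(inherits(series, "pv_series"))
  below <- which(series$v < threshold)
  if (length(below) > 0) {
    n_raw <- series$n[below[1]]
    if (n_raw < min_genes) {
      list(n = as.integer(min_genes), rule = "minimum-genes floor")
    } else {
      list(n = as.integer(n_raw), rule = "threshold")
    }
  } else {
    list(n = as.integer(series$n[which.min(series$v)] + 1L),
         rule = "minimum of V")
  }
}
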