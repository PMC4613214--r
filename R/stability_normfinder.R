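#' Model-based stability estimation (NormFinder-style)
#'
#' Decomposes the variation of log2 relative quantities into an intragroup
#' (noise) component and an intergroup (systematic, condition- or
#' replicate-linked) component, and scores each gene by the sum of its
#' estimated intergroup deviation and intragroup sampling error. Lower
#' stability values indicate more stable genes.
#'
#' The estimator works on `y = log2(q)` with `q` from [to_quantities()]:
#' each sample is centered across genes (`z = y - sample mean`), removing
#' sample-wide loading differences; per group the gene means `zbar` and
#' residual variances `s2` (n-1 denominator) are taken; the intragroup
#' variance is the bias-corrected
#' `sigma2 = max(0, s2 * (1 - 2/G) + sum_g(s2) / (G * (G - 1)))`;
#' intergroup deviations `d = zbar - mean over groups` are shrunk toward 0
#' by their sampling variance (empirical-Bayes factor
#' `gamma2 / (gamma2 + sigma2/n)`); the stability value is the group mean of
#' `|d_shrunk| + sqrt(sigma2 / n)`. With a single group the stability value
#' is the intragroup SD alone.
#'
#' @param ds A `cq_data` object (one tissue). Technical replicates are kept
#'   as-is: pass an unaveraged dataset with `groups = "tech_rep"`-like
#'   designs only after collapsing; the default here averages technical
#'   replicates and groups biological samples.
#' @param eff An [efficiency_table()] (genes default to E = 2).
#' @param groups Grouping variable: `"bio_rep"` (default; replicate series
#'   across the time course form the groups) or `"condition"`, or a factor
#'   with one value per sample column of the quantity matrix.
#' @return An object of class `normfinder_result`: list with `ranking`
#'   (`stability_ranking` tibble), `groups` (per-sample group labels),
#'   `diagnostics` (list of per gene x group matrices `sigma2` (intragroup
#'   variance), `d` (shrunken intergroup deviation), and group sizes `n`).
#' @export
normfinder_stability <- function(ds, eff = NULL, groups = "bio_rep") {
  stopifnot(inherits(ds, "cq_data"))
  .assert_single_tissue(ds, "normfinder_stability")
  if (has_tech_reps(ds)) ds <- average_technical_replicates(ds)
  q <- to_quantities(ds, eff)
  info <- .sample_info(q)
  if (is.character(groups) && length(groups) == 1) {
    if (!groups %in% names(info)) {
      stop("normfinder_stability: unknown grouping variable '", groups, "'",
           call. = FALSE)
    }
    grp <- factor(info[[groups]])
  } else {
    if (length(groups) != ncol(q)) {
      stop("normfinder_stability: `groups` must name an annotation column or ",
           "give one label per sample", call. = FALSE)
    }
    grp <- factor(groups)
  }
  G <- nrow(q)
  if (G < 3) stop("normfinder_stability: need at least 3 genes", call. = FALSE)
  if (any(table(grp) < 2)) {
    stop("normfinder_stability: every group needs at least 2 samples",
         call. = FALSE)
  }
  y <- log2(unclass(q))
  if (anyNA(y)) {
    keep <- colSums(is.na(y)) == 0
    if (sum(keep) < 2) {
      stop("normfinder_stability: too many samples with missing values",
           call. = FALSE)
    }
    warning("normfinder_stability: dropping ", sum(!keep),
            " sample(s) with missing values", call. = FALSE)
    y <- y[, keep, drop = FALSE]
    grp <- droplevels(grp[keep])
    if (any(table(grp) < 2)) {
      stop("normfinder_stability: every group needs at least 2 samples",
           call. = FALSE)
    }
  }
  z <- sweep(y, 2, colMeans(y))
  K <- nlevels(grp)
  n_k <- as.integer(table(grp))
  zbar <- sapply(levels(grp), function(k) rowMeans(z[, grp == k, drop = FALSE]))
  s2 <- sapply(levels(grp), function(k) apply(z[, grp == k, drop = FALSE], 1,
                                              stats::var))
  zbar <- matrix(zbar, nrow = G, dimnames = list(rownames(y), levels(grp)))
  s2 <- matrix(s2, nrow = G, dimnames = list(rownames(y), levels(grp)))
  # bias-corrected intragroup variance, clipped at zero
  sigma2 <- pmax(s2 * (1 - 2 / G) +
                   matrix(colSums(s2), G, K, byrow = TRUE) / (G * (G - 1)), 0)
  if (K == 1) {
    stability <- sqrt(sigma2[, 1])
    d_shrunk <- matrix(0, G, 1, dimnames = dimnames(zbar))
  } else {
    d <- zbar - rowMeans(zbar)
    v <- sweep(sigma2, 2, n_k, "/")           # sampling variance of zbar
    gamma2 <- pmax(apply(d, 1, stats::var) - rowMeans(v), 0)
    shrink <- gamma2 / (gamma2 + v)
    shrink[!is.finite(shrink)] <- 0           # gamma2 + v == 0
    d_shrunk <- d * shrink
    stability <- rowMeans(abs(d_shrunk) + sqrt(v))
  }
  out <- list(ranking = .make_ranking(rownames(y), unname(stability),
                                      "normfinder"),
              groups = grp,
              diagnostics = list(sigma2 = sigma2, d = d_shrunk, n = n_k))
  class(out) <- "normfinder_result"
  out
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("<normfinder_result> model-based stability ranking (",
      nlevels(x$groups), " groups)\n", sep = "")
  print(x$ranking)
  invisible(x)
}

#' @export
as_ranking.normfinder_result <- function(x, ...) x$ranking

#' Best two-gene combination under the model-based decomposition
#'
#' Searches all gene pairs for the combination whose averaged intergroup
#' deviations cancel best, scoring a pair by the group mean of
#' `|(d_i + d_j)/2| + sqrt((sigma2_i + sigma2_j) / (4 n))`. Requires at
#' least two groups (with one group there is no intergroup component and
#' the single-gene ranking applies).
#'
#' @param result A [normfinder_stability()] result.
#' @return A list with `genes` (character pair, sorted), `stability`
#'   (combined value), and `candidates` (tibble of all pairs, ascending).
#' @export
normfinder_best_pair <- function(result) {
  stopifnot(inherits(result, "normfinder_result"))
  if (nlevels(result$groups) < 2) {
    stop("normfinder_best_pair: needs at least 2 groups; with one group use ",
         "the single-gene ranking", call. = FALSE)
  }
  d <- result$diagnostics$d
  sigma2 <- result$diagnostics$sigma2
  n_k <- result$diagnostics$n
  genes <- sort(rownames(d))
  combs <- utils::combn(genes, 2)
  score <- apply(combs, 2, function(p) {
    dd <- (d[p[1], ] + d[p[2], ]) / 2
    se <- sqrt((sigma2[p[1], ] + sigma2[p[2], ]) / (4 * n_k))
    mean(abs(dd) + se)
  })
  tbl <- tibble::tibble(gene_1 = combs[1, ], gene_2 = combs[2, ],
                        stability = score)
  tbl <- tbl[order(tbl$stability, tbl$gene_1, tbl$gene_2), ]
  list(genes = c(tbl$gene_1[1], tbl$gene_2[1]),
       stability = tbl$stability[1],
       candidates = tbl)
}
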