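#' Pairwise delta-Ct stability analysis
#'
#' The comparative delta-Ct method ranks candidate reference genes by the
#' mean standard deviation (mSD) of their pairwise Cq differences: if
#' `Cq_i - Cq_j` is constant across samples, genes i and j are either both
#' stable or co-regulated; a fluctuating difference implicates at least one
#' of them. Each gene's mSD is the mean of its pairwise SDs against every
#' other gene; lower mSD means more stable. Raw Cq values are used directly,
#' without efficiency correction.
#'
#' @param ds A `cq_data` object restricted to one tissue. Technical
#'   replicates, if present, are averaged first. Every biological sample
#'   (condition x replicate) counts as one sample.
#' @return An object of class `dct_result`: a list with
#'   \describe{
#'     \item{ranking}{`stability_ranking` tibble (`gene, score, rank, tied,
#'       method`), score = mSD in cycles.}
#'     \item{sd_matrix}{Symmetric gene x gene matrix of pairwise delta-Ct
#'       SDs (n-1 denominator), zero diagonal.}
#'     \item{pairs}{Long tibble `pair_i, pair_j, sd, n_shared` (i < j).}
#'     \item{flagged_pairs}{Pairs with fewer than 3 shared samples.}
#'   }
#'   Pairs with fewer than 2 shared samples are an error.
#' @export
pairwise_dct <- function(ds) {
  stopifnot(inherits(ds, "cq_data"))
  .assert_single_tissue(ds, "pairwise_dct")
  mat <- .cq_matrix(ds)
  cq <- mat$cq
  G <- nrow(cq)
  if (G < 2) stop("pairwise_dct: need at least 2 genes", call. = FALSE)
  genes <- rownames(cq)
  sd_mat <- matrix(0, G, G, dimnames = list(genes, genes))
  pairs <- list()
  flagged <- character()
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      d <- cq[i, ] - cq[j, ]
      d <- d[!is.na(d)]
      if (length(d) < 2) {
        stop("pairwise_dct: genes '", genes[i], "' and '", genes[j],
             "' share fewer than 2 samples", call. = FALSE)
      }
      if (length(d) < 3) {
        flagged <- c(flagged, paste(genes[i], genes[j], sep = ":"))
      }
      s <- stats::sd(d)
      sd_mat[i, j] <- sd_mat[j, i] <- s
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        pair_i = genes[i], pair_j = genes[j], sd = s, n_shared = length(d))
    }
  }
  msd <- rowSums(sd_mat) / (G - 1)
  out <- list(ranking = .make_ranking(genes, unname(msd), "dct"),
              sd_matrix = sd_mat,
              pairs = dplyr::bind_rows(pairs),
              flagged_pairs = flagged)
  class(out) <- "dct_result"
  out
}

#' @export
print.dct_result <- function(x, ...) {
  cat("<dct_result> pairwise delta-Ct mSD ranking\n")
  print(x$ranking)
  invisible(x)
}

#' @export
as_ranking.dct_result <- function(x, ...) x$ranking

#' Plot-ready distributions of pairwise delta-Ct SDs
#'
#' For each gene, the vector of its G-1 pairwise SDs against the other
#' genes, plus box-and-whisker statistics (quartiles and 1.5 IQR whiskers
#' clamped to the data), ready for a box plot of delta-Ct spread.
#'
#' @param result A [pairwise_dct()] result.
#' @return A list with `values` (long tibble `gene, partner, sd`) and
#'   `stats` (tibble `gene, whisker_lo, q1, median, q3, whisker_hi`).
#' @export
dct_boxplot_data <- function(result) {
  stopifnot(inherits(result, "dct_result"))
  sd_mat <- result$sd_matrix
  genes <- rownames(sd_mat)
  values <- dplyr::bind_rows(lapply(genes, function(g) {
    tibble::tibble(gene = g, partner = setdiff(genes, g),
                   sd = unname(sd_mat[g, setdiff(genes, g)]))
  }))
  stats_tbl <- values |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(whisker_lo = 0, q1 = 0, median = 0, q3 = 0,
                     whisker_hi = 0, .groups = "drop")
  for (g in genes) {
    v <- values$sd[values$gene == g]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    lo <- min(v[v >= qs[1] - 1.5 * iqr])
    hi <- max(v[v <= qs[3] + 1.5 * iqr])
    stats_tbl[stats_tbl$gene == g, -1] <- as.list(c(lo, qs, hi))
  }
  list(values = values, stats = stats_tbl)
}
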