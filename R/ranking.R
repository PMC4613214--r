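# Shared helpers for per-gene stability rankings (lower score = more stable).

.make_ranking <- function(gene, score, method) {
  ord <- order(score, gene)             # ties broken by gene id, lexicographic
  rank <- integer(length(gene))
  rank[ord] <- seq_along(gene)
  tied <- duplicated(score) | duplicated(score, fromLast = TRUE)
  out <- tibble::tibble(gene = gene, score = score, rank = rank,
                        tied = tied, method = method)
  out <- out[order(out$rank), ]
  class(out) <- c("stability_ranking", class(tibble::tibble()))
  out
}

#' Extract a per-gene stability ranking
#'
#' Returns the common `gene, score, rank, tied, method` table from any of
#' the stability-method results, for printing, writing or rank aggregation.
#'
#' @param x A result from [pairwise_dct()], [normfinder_stability()],
#'   [genorm_rank()] or [graynorm_rank_all()].
#' @param ... Passed to methods.
#' @return A tibble of class `stability_ranking`, rows ordered by rank.
#' @export
as_ranking <- function(x, ...) UseMethod("as_ranking")

#' @export
as_ranking.stability_ranking <- function(x, ...) x

#' Gene identifiers in rank order (best first)
#'
#' For geNorm results the unresolvable final pair (both rank 1) is ordered
#' by the M value each gene had in the full starting set, which makes the
#' output a full permutation usable for rank aggregation.
#'
#' @param x A stability result accepted by [as_ranking()].
#' @return Character vector of gene ids, most stable first.
#' @export
ranking_order <- function(x) {
  r <- as_ranking(x)
  r$gene[order(r$rank, r$gene)]
}
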