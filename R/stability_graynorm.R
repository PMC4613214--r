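#' Control-calibrated relative quantities (GrayNorm input)
#'
#' Transforms Cq values to quantities relative to the untreated control
#' condition: `q_gs = E_g^(mean control Cq of g - Cq_gs)`, so each gene's
#' geometric-mean quantity over the control samples is exactly 1. A
#' normalization factor built from these quantities is therefore itself
#' calibrated to 1 at the control.
#'
#' @param ds A `cq_data` object, single tissue; technical replicates are
#'   averaged if present.
#' @param eff An [efficiency_table()].
#' @param control_condition Condition label of the control (e.g. time 0).
#' @return A genes x samples matrix of class `quantity_matrix` with
#'   attributes `sample_info`, `efficiency` and `control` (label).
#' @export
graynorm_quantities <- function(ds, eff = NULL, control_condition) {
  stopifnot(inherits(ds, "cq_data"))
  .assert_single_tissue(ds, "graynorm_quantities")
  if (has_tech_reps(ds)) ds <- average_technical_replicates(ds)
  mat <- .cq_matrix(ds)
  cq <- mat$cq
  info <- mat$info
  ctrl <- info$condition == control_condition
  if (!any(ctrl)) {
    stop("graynorm_quantities: control condition '", control_condition,
         "' not present", call. = FALSE)
  }
  ctrl_mean <- rowMeans(cq[, ctrl, drop = FALSE], na.rm = TRUE)
  no_ctrl <- !is.finite(ctrl_mean)
  if (any(no_ctrl)) {
    stop("graynorm_quantities: no control measurement for gene(s): ",
         paste(rownames(cq)[no_ctrl], collapse = ", "), call. = FALSE)
  }
  e <- .eff_vector(eff, rownames(cq))
  q <- e ^ (ctrl_mean - cq)
  structure(q, class = "quantity_matrix", efficiency = e,
            sample_info = info, control = control_condition,
            anchor_cq = ctrl_mean)
}

# Per-condition geometric means of 1/NF for one combination; the kernel
# shared by graynorm_score() and graynorm_rank_all().
.graynorm_condition_means <- function(lq, genes, condition) {
  log_nf <- colMeans(lq[genes, , drop = FALSE])
  tapply(-log_nf, condition, mean)    # log of geometric mean of 1/NF
}

#' Score one reference-gene combination (GrayNorm)
#'
#' Builds the combination's normalization factor (geometric mean of
#' control-calibrated quantities), averages 1/NF per condition
#' (geometric mean over the biological samples of each condition), and
#' summarizes how far those condition averages stray from 1.0: genes that
#' respond to the treatment drag 1/NF away from 1 and would imprint their
#' biological variation on every normalized gene of interest.
#'
#' @param ds,eff,control_condition As in [graynorm_quantities()].
#' @param combination Non-empty character vector of reference genes.
#' @return An object of class `combination_score`: list with `genes`,
#'   `size`, `condition_means` (tibble `condition, mean_inv_nf`),
#'   `cv_inter` (percent coefficient of variation of the condition
#'   averages) and `cumulative_deviation`
#'   (sum over non-control conditions of `|mean 1/NF - 1|`).
#' @export
graynorm_score <- function(ds, eff = NULL, combination, control_condition) {
  if (length(combination) == 0) {
    stop("graynorm_score: combination must be non-empty", call. = FALSE)
  }
  q <- graynorm_quantities(ds, eff, control_condition)
  unknown <- setdiff(combination, rownames(q))
  if (length(unknown) > 0) {
    stop("graynorm_score: unknown gene(s) in combination: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lq <- log(.as_quantity(q))
  info <- .sample_info(q)
  m <- exp(.graynorm_condition_means(lq, combination, info$condition))
  conds <- names(m)
  out <- list(genes = sort(combination), size = length(combination),
              condition_means = tibble::tibble(condition = conds,
                                               mean_inv_nf = as.numeric(m)),
              cv_inter = 100 * stats::sd(m) / mean(m),
              cumulative_deviation =
                sum(abs(m[conds != control_condition] - 1)))
  class(out) <- "combination_score"
  out
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("<combination_score> {%s}: cumulative deviation %.4f, cv_inter %.2f%%\n",
              paste(x$genes, collapse = ", "), x$cumulative_deviation,
              x$cv_inter))
  invisible(x)
}

#' Rank every reference-gene combination (GrayNorm)
#'
#' Enumerates all gene combinations within the requested size range, scores
#' each by [graynorm_score()] semantics, and ranks them ascending by
#' cumulative deviation (primary key), with ties broken by smaller
#' combination and then lexicographic gene list. The full enumeration is
#' the method's selling point: the best multi-gene normalizer can be read
#' straight off the table.
#'
#' @param ds,eff,control_condition As in [graynorm_quantities()].
#' @param min_size,max_size Combination size bounds (defaults 1 and G).
#' @param max_genes Enumeration guard: refuse more than this many genes
#'   (default 20, i.e. about a million combinations).
#' @return A tibble of class `graynorm_ranking` with columns
#'   `combination` (semicolon-joined sorted gene list), `size`, `cv_inter`,
#'   `cumulative_deviation`, `rank`, plus attribute `control`.
#' @export
graynorm_rank_all <- function(ds, eff = NULL, control_condition,
                              min_size = 1, max_size = NULL, max_genes = 20) {
  q <- graynorm_quantities(ds, eff, control_condition)
  lq <- log(.as_quantity(q))
  info <- .sample_info(q)
  genes <- sort(rownames(q))
  G <- length(genes)
  if (G > max_genes) {
    stop("graynorm_rank_all: ", G, " genes exceed the enumeration guard (",
         max_genes, "); raise `max_genes` to force 2^G enumeration",
         call. = FALSE)
  }
  if (is.null(max_size)) max_size <- G
  sizes <- seq(max(1, min_size), min(G, max_size))
  rows <- list()
  cond <- info$condition
  not_ctrl <- sort(unique(cond))
  not_ctrl <- not_ctrl[not_ctrl != control_condition]
  for (s in sizes) {
    combs <- utils::combn(genes, s)
    for (i in seq_len(ncol(combs))) {
      set <- combs[, i]
      m <- exp(.graynorm_condition_means(lq, set, cond))
      rows[[length(rows) + 1]] <- tibble::tibble(
        combination = paste(set, collapse = ";"),
        size = s,
        cv_inter = 100 * stats::sd(m) / mean(m),
        cumulative_deviation = sum(abs(m[not_ctrl] - 1)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$cumulative_deviation, out$size, out$combination), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "control") <- control_condition
  class(out) <- c("graynorm_ranking", class(tibble::tibble()))
  out
}

#' Pick the recommended combination from a GrayNorm ranking
#'
#' Returns the best-ranked combination containing at least `min_genes`
#' genes (default 3, the usual floor against co-regulation artifacts).
#'
#' @param ranked A [graynorm_rank_all()] result.
#' @param min_genes Minimum combination size.
#' @return Character vector of gene ids (the combination), with attribute
#'   `score` (its cumulative deviation) and `rank`.
#' @export
select_combination <- function(ranked, min_genes = 3) {
  stopifnot(inherits(ranked, "graynorm_ranking"))
  hit <- which(ranked$size >= min_genes)
  if (length(hit) == 0) {
    stop("select_combination: no combination with at least ", min_genes,
         " genes", call. = FALSE)
  }
  row <- ranked[hit[1], ]
  structure(strsplit(row$combination, ";", fixed = TRUE)[[1]],
            score = row$cumulative_deviation, rank = row$rank)
}

#' Per-gene GrayNorm ranking
#'
#' Ranks single genes by the cumulative deviation of their one-gene
#' normalization factor, giving GrayNorm a per-gene stability ranking
#' comparable (and aggregatable) with the other methods.
#'
#' @param ranked A [graynorm_rank_all()] result that includes size-1
#'   combinations (`min_size = 1`).
#' @return A `stability_ranking` tibble (score = cumulative deviation).
#' @export
graynorm_gene_ranking <- function(ranked) {
  stopifnot(inherits(ranked, "graynorm_ranking"))
  singles <- ranked[ranked$size == 1, ]
  if (nrow(singles) == 0) {
    stop("graynorm_gene_ranking: ranking holds no single-gene combinations",
         call. = FALSE)
  }
  .make_ranking(singles$combination, singles$cumulative_deviation, "graynorm")
}
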