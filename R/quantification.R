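#' Relative quantity of a gene of interest
#'
#' Efficiency-corrected relative quantification against the control
#' condition: `RQ_s = E^(mean control Cq - Cq_s)`, so a sample amplifying
#' one cycle earlier than the control mean has RQ = E (induction gives
#' RQ > 1), and the geometric-mean RQ over the control samples is exactly 1.
#'
#' @param ds A `cq_data` object (one tissue; technical replicates are
#'   averaged if present).
#' @param eff An [efficiency_table()].
#' @param goi Gene of interest (must be present in `ds`).
#' @param control_condition Control condition label.
#' @return Tibble `sample, condition, bio_rep, rq` with attributes `goi`
#'   and `control`.
#' @export
relative_quantity <- function(ds, eff = NULL, goi, control_condition) {
  stopifnot(inherits(ds, "cq_data"))
  if (!goi %in% ds$gene) {
    stop("relative_quantity: gene '", goi, "' not in dataset", call. = FALSE)
  }
  q <- graynorm_quantities(ds, eff, control_condition)
  if (!goi %in% rownames(q)) {
    stop("relative_quantity: gene '", goi, "' not in dataset", call. = FALSE)
  }
  info <- .sample_info(q)
  out <- tibble::tibble(sample = info$sample, condition = info$condition,
                        bio_rep = info$bio_rep,
                        rq = unname(unclass(q)[goi, ]))
  attr(out, "goi") <- goi
  attr(out, "control") <- control_condition
  out
}

#' Normalize a gene of interest by a normalization factor
#'
#' Divides per-sample relative quantities by the per-sample normalization
#' factor of a reference-gene set and adds the log2 display transform
#' (log2 of 1 is 0 = unchanged expression).
#'
#' @param rq A [relative_quantity()] result.
#' @param nf A [normalization_factor()] result on the same samples (built
#'   from control-calibrated quantities so that it is itself calibrated).
#' @return An object of class `expression_profile`: tibble `sample,
#'   condition, bio_rep, rq, nf, normalized, log2_normalized`, attributes
#'   `goi`, `reference_genes`, `control`.
#' @export
normalize_expression <- function(rq, nf) {
  stopifnot(inherits(nf, "normalization_factor"))
  if (!setequal(rq$sample, nf$sample)) {
    stop("normalize_expression: sample sets of RQ and NF differ", call. = FALSE)
  }
  nf_s <- nf$nf[match(rq$sample, nf$sample)]
  out <- rq
  out$nf <- nf_s
  out$normalized <- out$rq / nf_s
  out$log2_normalized <- log2(out$normalized)
  attr(out, "goi") <- attr(rq, "goi", exact = TRUE)
  attr(out, "reference_genes") <- attr(nf, "genes", exact = TRUE)
  attr(out, "control") <- attr(rq, "control", exact = TRUE)
  class(out) <- c("expression_profile", class(tibble::tibble()))
  out
}

#' Fold discrepancy between two reference genes
#'
#' The quantification error committed by normalizing against a reference
#' gene with `var_a` cycles of treatment-driven variation instead of one
#' with `var_b` cycles: `base^(var_a - var_b)`. One spare cycle of
#' reference-gene variation corresponds to a factor `base` (~2) on every
#' normalized fold change.
#'
#' @param var_a,var_b Cycles of variation of the two candidate references.
#' @param base Amplification base, default 2 (perfect doubling).
#' @return The fold discrepancy, `base^(var_a - var_b)`.
#' @export
fold_discrepancy <- function(var_a, var_b, base = 2) {
  if (base <= 1) stop("fold_discrepancy: base must exceed 1", call. = FALSE)
  base ^ (var_a - var_b)
}

#' Compare normalization strategies for genes of interest
#'
#' Computes, for each gene of interest and candidate strategy (a named
#' reference-gene set, or `"none"` for non-normalized), the per-condition
#' mean and standard error of log2 expression over biological replicates,
#' plus a per-strategy accuracy statistic: the mean over genes of interest
#' and conditions of `|log2(normalized) - log2(non-normalized)|`. A good
#' reference set corrects technical variation without imprinting its own
#' biological response, so smaller deviations from the non-normalized
#' profile indicate less reference-carried bias.
#'
#' @param ds A `cq_data` object (one tissue).
#' @param eff An [efficiency_table()].
#' @param gois Character vector of genes of interest.
#' @param strategies Named list; each element is a character vector of
#'   reference genes or the string `"none"`.
#' @param control_condition Control condition label.
#' @return A list with `profiles` (tibble `goi, condition, strategy,
#'   mean_log2, se_log2`) and `summary` (tibble `strategy,
#'   mean_abs_deviation`, ascending).
#' @export
compare_strategies <- function(ds, eff = NULL, gois, strategies,
                               control_condition) {
  stopifnot(inherits(ds, "cq_data"), length(gois) > 0, length(strategies) > 0)
  if (is.null(names(strategies)) || any(names(strategies) == "")) {
    stop("compare_strategies: strategies must be a named list", call. = FALSE)
  }
  q <- graynorm_quantities(ds, eff, control_condition)
  ref_sets <- strategies[!vapply(strategies, function(s)
    identical(s, "none") || length(s) == 0, logical(1))]
  for (nm in names(ref_sets)) {
    unknown <- setdiff(ref_sets[[nm]], rownames(q))
    if (length(unknown) > 0) {
      stop("compare_strategies: strategy '", nm, "' names unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  missing_goi <- setdiff(gois, rownames(q))
  if (length(missing_goi) > 0) {
    stop("compare_strategies: gene(s) of interest not in dataset: ",
         paste(missing_goi, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (g in gois) {
    rq <- relative_quantity(ds, eff, g, control_condition)
    for (nm in names(strategies)) {
      set <- strategies[[nm]]
      if (identical(set, "none") || length(set) == 0) {
        log2_val <- log2(rq$rq)
      } else {
        nf <- normalization_factor(q, set)
        log2_val <- log2(rq$rq / nf$nf[match(rq$sample, nf$sample)])
      }
      per_cond <- tibble::tibble(condition = rq$condition, v = log2_val) |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(mean_log2 = mean(.data$v),
                         se_log2 = stats::sd(.data$v) / sqrt(dplyr::n()),
                         .groups = "drop")
      rows[[length(rows) + 1]] <- tibble::tibble(
        goi = g, condition = per_cond$condition, strategy = nm,
        mean_log2 = per_cond$mean_log2, se_log2 = per_cond$se_log2)
    }
  }
  profiles <- dplyr::bind_rows(rows)
  none_names <- names(strategies)[vapply(strategies, function(s)
    identical(s, "none") || length(s) == 0, logical(1))]
  base <- profiles[profiles$strategy %in% none_names[1], ]
  if (nrow(base) == 0) {
    rows0 <- list()
    for (g in gois) {
      rq <- relative_quantity(ds, eff, g, control_condition)
      per_cond <- tibble::tibble(condition = rq$condition, v = log2(rq$rq)) |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(mean_log2 = mean(.data$v), .groups = "drop")
      rows0[[length(rows0) + 1]] <- tibble::tibble(
        goi = g, condition = per_cond$condition,
        mean_log2_none = per_cond$mean_log2)
    }
    base <- dplyr::bind_rows(rows0)
  } else {
    base <- base[, c("goi", "condition", "mean_log2")]
    names(base)[3] <- "mean_log2_none"
  }
  dev <- dplyr::left_join(profiles, base, by = c("goi", "condition")) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(mean_abs_deviation =
                       mean(abs(.data$mean_log2 - .data$mean_log2_none)),
                     .groups = "drop") |>
    dplyr::arrange(.data$mean_abs_deviation, .data$strategy)
  list(profiles = profiles, summary = dev)
}
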