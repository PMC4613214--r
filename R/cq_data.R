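#' Construct a validated Cq dataset
#'
#' A Cq dataset is a long-format table of quantification-cycle (Cq) values,
#' one row per gene and reaction well, annotated with the sample's tissue,
#' condition (e.g. a time point of a stress treatment), biological replicate
#' and, optionally, technical replicate. It is the common input of every
#' stability method in the package.
#'
#' @param df A data frame with columns `gene`, `sample`, `tissue`,
#'   `condition`, `bio_rep`, `cq` and optionally `tech_rep`. `sample` must
#'   uniquely identify a well within a gene (i.e. `(gene, sample)` pairs are
#'   unique). Missing Cq values are allowed (`NA`); present values must be
#'   finite and lie in the open interval (0, 45) cycles.
#'
#' @return A tibble of class `cq_data`, columns in canonical order.
#' @export
cq_dataset <- function(df) {
  required <- c("gene", "sample", "tissue", "condition", "bio_rep", "cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cq_dataset: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_tech <- "tech_rep" %in% names(df)
  cols <- c("gene", "sample", "tissue", "condition", "bio_rep",
            if (has_tech) "tech_rep", "cq")
  df <- tibble::as_tibble(df)[cols]
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  df$tissue <- as.character(df$tissue)
  df$condition <- as.character(df$condition)
  df$bio_rep <- as.integer(df$bio_rep)
  if (has_tech) df$tech_rep <- as.integer(df$tech_rep)
  df$cq <- as.double(df$cq)

  present <- !is.na(df$cq)
  bad <- present & (!is.finite(df$cq) | df$cq <= 0 | df$cq >= 45)
  if (any(bad)) {
    stop("cq_dataset: Cq values must be finite and in (0, 45); offending rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$gene) || anyNA(df$sample) || anyNA(df$tissue) || anyNA(df$condition)) {
    stop("cq_dataset: gene, sample, tissue and condition must be non-missing",
         call. = FALSE)
  }
  if (anyNA(df$bio_rep) || any(df$bio_rep < 1L)) {
    stop("cq_dataset: bio_rep must be a positive integer", call. = FALSE)
  }
  if (has_tech && (anyNA(df$tech_rep) || any(df$tech_rep < 1L))) {
    stop("cq_dataset: tech_rep must be a positive integer", call. = FALSE)
  }
  key <- paste(df$gene, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("gene", "sample")]
    stop("cq_dataset: duplicate (gene, sample) keys, e.g. gene '",
         dup$gene[1], "' sample '", dup$sample[1], "'", call. = FALSE)
  }
  if (length(unique(df$gene)) < 2 || length(unique(df$sample)) < 2) {
    stop("cq_dataset: need at least 2 genes and 2 samples", call. = FALSE)
  }
  class(df) <- c("cq_data", class(tibble::tibble()))
  df
}

#' @export
print.cq_data <- function(x, ...) {
  cat(sprintf("<cq_data> %d genes x %d samples (%d tissues, %d conditions)%s\n",
              length(unique(x$gene)), length(unique(x$sample)),
              length(unique(x$tissue)), length(unique(x$condition)),
              if (has_tech_reps(x)) ", technical replicates present" else ""))
  NextMethod()
}

#' Does the dataset still carry a technical-replicate dimension?
#' @param ds A `cq_data` object.
#' @return Logical scalar.
#' @export
has_tech_reps <- function(ds) "tech_rep" %in% names(ds)

#' Restrict a Cq dataset to one tissue
#'
#' The stability methods analyse one cohort (tissue) at a time; use this to
#' slice a multi-tissue dataset before ranking.
#'
#' @param ds A `cq_data` object.
#' @param tissue Tissue label to keep.
#' @return A `cq_data` object containing only that tissue.
#' @export
filter_tissue <- function(ds, tissue) {
  stopifnot(inherits(ds, "cq_data"))
  if (!tissue %in% ds$tissue) {
    stop("filter_tissue: tissue '", tissue, "' not present in dataset",
         call. = FALSE)
  }
  cq_dataset(ds[ds$tissue == tissue, , drop = FALSE])
}

.assert_single_tissue <- function(ds, what) {
  tis <- unique(ds$tissue)
  if (length(tis) > 1) {
    stop(what, ": dataset spans ", length(tis),
         " tissues; analyse one cohort at a time (see filter_tissue())",
         call. = FALSE)
  }
  invisible(tis)
}

#' Average technical replicates
#'
#' Collapses technical (well-level) replicates to one Cq per gene and
#' biological sample by arithmetic mean of the present values. Samples whose
#' technical replicates are all missing stay missing. Sample identifiers are
#' rewritten as `tissue.condition.b<bio_rep>`.
#'
#' @param ds A `cq_data` object. Returned unchanged (except classes) when no
#'   technical-replicate column is present.
#' @return A `cq_data` object without a `tech_rep` column.
#' @export
average_technical_replicates <- function(ds) {
  stopifnot(inherits(ds, "cq_data"))
  if (!has_tech_reps(ds)) return(ds)
  out <- ds |>
    dplyr::group_by(.data$gene, .data$tissue, .data$condition, .data$bio_rep) |>
    dplyr::summarise(cq = if (all(is.na(.data$cq))) NA_real_
                     else mean(.data$cq[!is.na(.data$cq)]),
                     .groups = "drop") |>
    dplyr::mutate(sample = sprintf("%s.%s.b%d", .data$tissue, .data$condition,
                                   .data$bio_rep)) |>
    dplyr::arrange(.data$gene, .data$tissue, .data$condition, .data$bio_rep)
  cq_dataset(out)
}

# Gene x sample Cq matrix plus per-sample annotations, for the numeric kernels.
.cq_matrix <- function(ds) {
  if (has_tech_reps(ds)) ds <- average_technical_replicates(ds)
  genes <- sort(unique(ds$gene))
  info <- dplyr::distinct(ds[, c("sample", "tissue", "condition", "bio_rep")]) |>
    dplyr::arrange(.data$tissue, .data$condition, .data$bio_rep, .data$sample)
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(info),
              dimnames = list(genes, info$sample))
  m[cbind(match(ds$gene, genes), match(ds$sample, info$sample))] <- ds$cq
  list(cq = m, info = info)
}

#' Per-gene descriptive summaries of Cq variation
#'
#' Summarizes each gene's Cq level and its condition-driven variation.
#' Biological (and technical) replicates are averaged first, so that `range`
#' measures treatment-driven change in cycles rather than replicate scatter.
#'
#' @param ds A `cq_data` object.
#' @param group_by `"tissue"` (default) for one summary row per gene and
#'   tissue, or `"all"` to pool every tissue.
#' @return A tibble with columns `gene` (`tissue`), `mean_cq`, `sd_cq`,
#'   `min_cq`, `max_cq`, `range_cq`, computed over condition means. `sd_cq`
#'   uses the n-1 denominator.
#' @export
summarize_cq <- function(ds, group_by = c("tissue", "all")) {
  stopifnot(inherits(ds, "cq_data"))
  group_by <- match.arg(group_by)
  if (has_tech_reps(ds)) ds <- average_technical_replicates(ds)
  cond_means <- ds |>
    dplyr::group_by(.data$gene, .data$tissue, .data$condition) |>
    dplyr::summarise(cq = if (all(is.na(.data$cq))) NA_real_
                     else mean(.data$cq[!is.na(.data$cq)]),
                     .groups = "drop")
  keys <- if (group_by == "tissue") c("gene", "tissue") else "gene"
  out <- cond_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_cq = mean(.data$cq, na.rm = TRUE),
      sd_cq = stats::sd(.data$cq, na.rm = TRUE),
      min_cq = suppressWarnings(min(.data$cq, na.rm = TRUE)),
      max_cq = suppressWarnings(max(.data$cq, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::mutate(range_cq = .data$max_cq - .data$min_cq) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  out$sd_cq[is.na(out$sd_cq)] <- 0
  out
}
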