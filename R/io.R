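#' Read a Cq table from disk
#'
#' Reads CSV or TSV tables of quantification cycles in either of two
#' layouts. The long layout has one row per well with columns
#' `gene,sample,tissue,condition,bio_rep,tech_rep,cq` (`tech_rep` optional).
#' The wide layout has genes as rows and samples as columns (first column
#' `gene`) and needs a sidecar annotation table with columns
#' `sample,tissue,condition,bio_rep` (+ optional `tech_rep`). Decimal
#' separator is always the dot; empty cells and `NA` are missing values;
#' lines starting with `#` are ignored (provenance headers).
#'
#' @param path Path to the table. Files ending in `.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated.
#' @param layout `"long"` (default) or `"wide"`.
#' @param annotations For `layout = "wide"`, path to the sample-annotation
#'   table.
#' @return A validated `cq_data` object.
#' @export
read_cq_table <- function(path, layout = c("long", "wide"), annotations = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("read_cq_table: file not found: ", path, call. = FALSE)
  }
  raw <- .read_delim(path)
  if (layout == "long") {
    required <- c("gene", "sample", "tissue", "condition", "bio_rep", "cq")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("read_cq_table: missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    raw$cq <- .parse_cq(raw$cq, "cq")
    cq_dataset(raw)
  } else {
    if (is.null(annotations)) {
      stop("read_cq_table: wide layout needs an `annotations` table", call. = FALSE)
    }
    if (names(raw)[1] != "gene") {
      stop("read_cq_table: missing required column(s): gene", call. = FALSE)
    }
    ann <- .read_delim(annotations)
    need <- c("sample", "tissue", "condition", "bio_rep")
    missing_cols <- setdiff(need, names(ann))
    if (length(missing_cols) > 0) {
      stop("read_cq_table: annotation table missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    long <- tidyr::pivot_longer(raw, -"gene", names_to = "sample",
                                values_to = "cq")
    long$cq <- .parse_cq(as.character(long$cq), "cq")
    unknown <- setdiff(long$sample, ann$sample)
    if (length(unknown) > 0) {
      stop("read_cq_table: samples without annotations: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cq_dataset(dplyr::left_join(long, ann, by = "sample"))
  }
}

.read_delim <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, comment = "#",
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

# Locale-independent numeric parsing with row-numbered errors; ""/"NA" -> NA.
.parse_cq <- function(x, col) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop("read_cq_table: non-numeric ", col, " value '", x[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

#' Read a per-gene efficiency table
#'
#' @param path CSV/TSV with columns `gene,efficiency`.
#' @return An [efficiency_table()].
#' @export
read_efficiency_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_efficiency_table: file not found: ", path, call. = FALSE)
  }
  raw <- .read_delim(path)
  if (!all(c("gene", "efficiency") %in% names(raw))) {
    stop("read_efficiency_table: need columns gene and efficiency", call. = FALSE)
  }
  raw$efficiency <- .parse_cq(raw$efficiency, "efficiency")
  efficiency_table(raw)
}

#' Write a result table to CSV/TSV
#'
#' Generic writer for the package's tabular results with deterministic row
#' and column order so that identical analyses produce byte-identical files.
#' Cq datasets round-trip losslessly through [read_cq_table()].
#'
#' @param x Object to write (`cq_data`, a ranking tibble, any data frame).
#' @param path Output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @param header_lines Optional character vector of provenance lines written
#'   before the table, each prefixed with `"# "`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, format = c("csv", "tsv"), header_lines = NULL) {
  UseMethod("write_table")
}

.write_delim <- function(df, path, format, header_lines) {
  format <- match.arg(format, c("csv", "tsv"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("write_table: cannot open '", path, "' for writing: ",
         conditionMessage(e), call. = FALSE)
  })
  close(con)
  if (!is.null(header_lines)) {
    readr::write_lines(paste0("# ", header_lines), path)
  }
  delim <- if (format == "tsv") "\t" else ","
  readr::write_delim(df, path, delim = delim, na = "NA",
                     append = !is.null(header_lines),
                     col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.cq_data <- function(x, path, format = c("csv", "tsv"),
                                header_lines = NULL) {
  ord <- c("gene", "tissue", "condition", "bio_rep",
           if (has_tech_reps(x)) "tech_rep")
  df <- dplyr::arrange(tibble::as_tibble(x),
                       dplyr::across(dplyr::all_of(ord)))
  .write_delim(df, path, format, header_lines)
}

#' @rdname write_table
#' @export
write_table.stability_ranking <- function(x, path, format = c("csv", "tsv"),
                                          header_lines = NULL) {
  df <- dplyr::arrange(tibble::as_tibble(x), .data$rank, .data$gene)
  .write_delim(df, path, format, header_lines)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(x, path, format = c("csv", "tsv"),
                                   header_lines = NULL) {
  .write_delim(tibble::as_tibble(x), path, format, header_lines)
}
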