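#' Construct a per-gene PCR efficiency table
#'
#' Amplification efficiency E is expressed as fold amplification per cycle
#' (2 = perfect doubling), the scale on which standard-curve slopes are
#' usually reported (typically 1.9--2.1), not as a percentage.
#'
#' @param x Either a data frame with columns `gene` and `efficiency`, or a
#'   named numeric vector of efficiencies.
#' @return A tibble of class `efficiency_table` with columns `gene`,
#'   `efficiency`. Efficiencies must exceed 1; values outside \[1.6, 2.2\]
#'   trigger a warning (plausibility check, not an error).
#' @export
efficiency_table <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(gene = names(x), efficiency = unname(x))
  }
  if (!all(c("gene", "efficiency") %in% names(x))) {
    stop("efficiency_table: need columns gene and efficiency", call. = FALSE)
  }
  out <- tibble::tibble(gene = as.character(x$gene),
                        efficiency = as.double(x$efficiency))
  if (anyDuplicated(out$gene)) {
    stop("efficiency_table: duplicate gene entries", call. = FALSE)
  }
  if (anyNA(out$efficiency) || any(out$efficiency <= 1)) {
    stop("efficiency_table: every efficiency must be > 1 (fold per cycle)",
         call. = FALSE)
  }
  off <- out$efficiency < 1.6 | out$efficiency > 2.2
  if (any(off)) {
    warning("efficiency_table: efficiency outside the typical [1.6, 2.2] range for ",
            paste(out$gene[off], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("efficiency_table", class(out))
  out
}

# Named efficiency vector for a gene set; absent genes default to 2.0 with a
# warning (perfect doubling).
.eff_vector <- function(eff, genes) {
  if (is.null(eff)) eff <- efficiency_table(tibble::tibble(gene = character(),
                                                           efficiency = double()))
  stopifnot(inherits(eff, "efficiency_table"))
  e <- stats::setNames(rep(2.0, length(genes)), genes)
  hit <- intersect(genes, eff$gene)
  e[hit] <- eff$efficiency[match(hit, eff$gene)]
  missing <- setdiff(genes, eff$gene)
  if (length(missing) > 0) {
    warning("no efficiency entry for ", paste(missing, collapse = ", "),
            "; assuming E = 2.0", call. = FALSE)
  }
  e
}

#' Transform Cq values to relative quantities
#'
#' Converts quantification cycles to efficiency-corrected relative
#' quantities `q = E^-(Cq - min Cq)`, anchored per gene so that the sample
#' with the lowest Cq (highest abundance) has quantity exactly 1. This is
#' the standard input transform of quantity-based stability methods.
#'
#' @param ds A `cq_data` object with technical replicates already averaged
#'   (see [average_technical_replicates()]) and a single tissue.
#' @param eff An [efficiency_table()]; genes without an entry fall back to
#'   E = 2 with a warning.
#' @return A numeric matrix (genes x samples) of class `quantity_matrix`,
#'   values in (0, 1], with attributes `anchor_cq` (per-gene minimum Cq used
#'   as anchor), `efficiency` (named vector) and `sample_info` (tibble of
#'   per-sample annotations).
#' @export
to_quantities <- function(ds, eff = NULL) {
  stopifnot(inherits(ds, "cq_data"))
  if (has_tech_reps(ds)) {
    stop("to_quantities: average technical replicates first ",
         "(average_technical_replicates())", call. = FALSE)
  }
  mat <- .cq_matrix(ds)
  cq <- mat$cq
  all_missing <- rowSums(!is.na(cq)) == 0
  if (any(all_missing)) {
    stop("to_quantities: gene(s) with all Cq missing: ",
         paste(rownames(cq)[all_missing], collapse = ", "), call. = FALSE)
  }
  e <- .eff_vector(eff, rownames(cq))
  anchor <- apply(cq, 1, min, na.rm = TRUE)
  q <- e ^ -(cq - anchor)   # e and anchor recycle down columns (gene-wise)
  structure(q, class = "quantity_matrix", anchor_cq = anchor,
            efficiency = e, sample_info = mat$info)
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("<quantity_matrix> %d genes x %d samples (per-gene max = 1)\n",
              nrow(x), ncol(x)))
  print(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE])
  invisible(x)
}

.sample_info <- function(q) attr(q, "sample_info", exact = TRUE)
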