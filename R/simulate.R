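#' Build a simulation configuration for synthetic Cq data
#'
#' Defines a qPCR experiment with known ground truth. Each reference-gene
#' candidate has a baseline level `mean_cq` (cycles), an amplification
#' efficiency, a condition-response amplitude `beta` (cycles; its absolute
#' value is the gene's true treatment-driven cycle variation) and a
#' response `shape` over the ordered conditions. Genes of interest are
#' specified by a true log2 fold-change trajectory (`amplitude_log2` times
#' the shape), which the generator converts to Cq shifts through the
#' gene's own efficiency. Noise is Gaussian on the Cq scale: a biological
#' deviate shared by all genes of a biological sample (`sigma_b`,
#' emulating RNA input and RT differences) plus an independent technical
#' deviate per well (`sigma_t`).
#'
#' Response shapes (unit range, zero at the first/control condition):
#' `"flat"` (no response), `"ramp"` (monotone increase) and `"pulse"`
#' (up-then-down, peaking mid-course). Genes given the same shape are
#' co-regulated by construction.
#'
#' @param genes Data frame with columns `gene, mean_cq, efficiency, beta,
#'   shape`.
#' @param gois Optional data frame with columns `gene, mean_cq, efficiency,
#'   amplitude_log2, shape`.
#' @param tissues Character vector of tissue labels.
#' @param conditions Ordered character vector of condition labels (>= 2);
#'   the first is the control.
#' @param n_bio,n_tech Biological/technical replicate counts (>= 1).
#' @param sigma_b,sigma_t Biological and technical noise SD in cycles
#'   (>= 0).
#' @param seed Integer seed making the simulation deterministic.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genes, gois = NULL,
                       tissues = c("leaf", "stem", "root"),
                       conditions = c("0h", "1h", "3h", "6h", "9h", "12h"),
                       n_bio = 3, n_tech = 3,
                       sigma_b = 0.2, sigma_t = 0.1, seed = 1) {
  problems <- character()
  need <- c("gene", "mean_cq", "efficiency", "beta", "shape")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    problems <- c(problems, paste("`genes` needs columns",
                                  paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(genes$gene)) problems <- c(problems, "duplicate gene names")
    if (!all(genes$shape %in% c("flat", "ramp", "pulse"))) {
      problems <- c(problems, "unknown shape (use flat, ramp or pulse)")
    }
    if (any(genes$efficiency <= 1)) problems <- c(problems, "efficiency must be > 1")
  }
  if (!is.null(gois)) {
    need_g <- c("gene", "mean_cq", "efficiency", "amplitude_log2", "shape")
    if (!is.data.frame(gois) || !all(need_g %in% names(gois))) {
      problems <- c(problems, paste("`gois` needs columns",
                                    paste(need_g, collapse = ", ")))
    } else if (!all(gois$shape %in% c("flat", "ramp", "pulse"))) {
      problems <- c(problems, "unknown GOI shape (use flat, ramp or pulse)")
    }
  }
  if (length(conditions) < 2) problems <- c(problems, "need at least 2 conditions")
  if (n_bio < 1 || n_tech < 1) problems <- c(problems, "replicate counts must be >= 1")
  if (sigma_b < 0 || sigma_t < 0) problems <- c(problems, "noise SDs must be >= 0")
  if (length(problems) > 0) {
    stop("sim_config: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(genes = tibble::as_tibble(genes),
                 gois = if (is.null(gois)) NULL else tibble::as_tibble(gois),
                 tissues = tissues, conditions = conditions,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 sigma_b = sigma_b, sigma_t = sigma_t,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Response profile over C ordered conditions: unit range, zero at condition 1.
.response_shape <- function(shape, C) {
  x <- (seq_len(C) - 1) / (C - 1)
  switch(shape,
         flat = rep(0, C),
         ramp = x,
         pulse = { y <- sin(pi * x); y / max(y) },
         stop("unknown shape: ", shape, call. = FALSE))
}

#' Simulate a Cq dataset with known ground truth
#'
#' Draws `Cq = mean_cq + beta * f(condition) + b + e`, with `b` a biological
#' deviate shared by every gene measured on the same biological sample
#' (`N(0, sigma_b)`) and `e` an independent technical deviate per well
#' (`N(0, sigma_t)`). Genes of interest enter on the quantity scale: their
#' true log2 fold change at condition c is `amplitude_log2 * f(c)`, so
#' their Cq shift is `-amplitude_log2 * f(c) / log2(E)`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cq_simulation` with
#'   \describe{
#'     \item{dataset}{`cq_data` long table (reference genes + GOIs).}
#'     \item{efficiencies}{[efficiency_table()] of all simulated genes.}
#'     \item{truth}{List: `genes` (tibble `gene, role, beta, shape,
#'       true_range` in cycles) and `goi_log2fc` (tibble `gene, condition,
#'       log2fc`).}
#'     \item{config}{The configuration used.}
#'   }
#' @export
simulate_cq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  C <- length(config$conditions)
  gene_tbl <- config$genes
  goi_tbl <- config$gois
  shapes_ref <- lapply(gene_tbl$shape, .response_shape, C = C)
  rows <- list()
  truth_goi <- list()
  for (tis in config$tissues) {
    # biological deviate per (condition, bio rep), shared across genes
    b <- matrix(stats::rnorm(C * config$n_bio, 0, config$sigma_b),
                C, config$n_bio)
    for (gi in seq_len(nrow(gene_tbl))) {
      f <- shapes_ref[[gi]]
      mu_c <- gene_tbl$mean_cq[gi] + gene_tbl$beta[gi] * f
      rows[[length(rows) + 1]] <- .sim_wells(gene_tbl$gene[gi], tis, config,
                                             mu_c, b)
    }
    if (!is.null(goi_tbl)) {
      for (gi in seq_len(nrow(goi_tbl))) {
        f <- .response_shape(goi_tbl$shape[gi], C)
        l2 <- goi_tbl$amplitude_log2[gi] * f
        mu_c <- goi_tbl$mean_cq[gi] - l2 / log2(goi_tbl$efficiency[gi])
        rows[[length(rows) + 1]] <- .sim_wells(goi_tbl$gene[gi], tis, config,
                                               mu_c, b)
      }
    }
  }
  if (!is.null(goi_tbl)) {
    for (gi in seq_len(nrow(goi_tbl))) {
      f <- .response_shape(goi_tbl$shape[gi], C)
      truth_goi[[gi]] <- tibble::tibble(gene = goi_tbl$gene[gi],
                                        condition = config$conditions,
                                        log2fc = goi_tbl$amplitude_log2[gi] * f)
    }
  }
  eff <- efficiency_table(tibble::tibble(
    gene = c(gene_tbl$gene, if (!is.null(goi_tbl)) goi_tbl$gene),
    efficiency = c(gene_tbl$efficiency,
                   if (!is.null(goi_tbl)) goi_tbl$efficiency)))
  truth_genes <- tibble::tibble(
    gene = c(gene_tbl$gene, if (!is.null(goi_tbl)) goi_tbl$gene),
    role = c(rep("reference", nrow(gene_tbl)),
             if (!is.null(goi_tbl)) rep("goi", nrow(goi_tbl))),
    beta = c(gene_tbl$beta,
             if (!is.null(goi_tbl)) -goi_tbl$amplitude_log2 /
               log2(goi_tbl$efficiency)),
    shape = c(gene_tbl$shape, if (!is.null(goi_tbl)) goi_tbl$shape),
    true_range = abs(c(gene_tbl$beta,
                       if (!is.null(goi_tbl)) goi_tbl$amplitude_log2 /
                         log2(goi_tbl$efficiency))))
  structure(list(dataset = cq_dataset(dplyr::bind_rows(rows)),
                 efficiencies = eff,
                 truth = list(genes = truth_genes,
                              goi_log2fc = if (length(truth_goi) > 0)
                                dplyr::bind_rows(truth_goi) else NULL),
                 config = config),
            class = "cq_simulation")
}

.sim_wells <- function(gene, tissue, config, mu_c, b) {
  C <- length(config$conditions)
  grid <- expand.grid(tech_rep = seq_len(config$n_tech),
                      bio_rep = seq_len(config$n_bio),
                      ci = seq_len(C))
  cq <- mu_c[grid$ci] + b[cbind(grid$ci, grid$bio_rep)] +
    stats::rnorm(nrow(grid), 0, config$sigma_t)
  tibble::tibble(
    gene = gene,
    sample = sprintf("%s.%s.b%d.t%d", tissue, config$conditions[grid$ci],
                     grid$bio_rep, grid$tech_rep),
    tissue = tissue,
    condition = config$conditions[grid$ci],
    bio_rep = grid$bio_rep,
    tech_rep = grid$tech_rep,
    cq = cq)
}

#' Default synthetic panel: salt-stress time course
#'
#' Convenience preset emulating a typical salt-stress validation design:
#' ten candidate reference genes plus nine salt-responsive genes of
#' interest, measured in three tissues over six time points (0--12 h, time
#' 0 = control) with three biological and three technical replicates.
#' Baseline Cq levels span roughly 19.6--32.4 cycles and the reference
#' genes' treatment-driven variation spans about 0.5--3.3 cycles, with
#' `TUB` and `Actin` designated the most condition-responsive candidates.
#'
#' @param seed Integer seed.
#' @return A `cq_simulation` (see [simulate_cq()]).
#' @export
sim_salt_timecourse <- function(seed = 1) {
  genes <- tibble::tribble(
    ~gene,    ~mean_cq, ~efficiency, ~beta, ~shape,
    "60S",    24.0,     1.972,        0.9,  "ramp",
    "Actin",  23.5,     2.027,        2.5,  "pulse",
    "EF1a",   21.5,     1.896,        1.3,  "ramp",
    "eIF-5A", 23.0,     1.965,        0.7,  "pulse",
    "GAPDH",  24.5,     1.904,       -1.1,  "ramp",
    "GIIa",   26.0,     2.009,        1.8,  "ramp",
    "HIS",    25.0,     1.968,        0.55, "ramp",
    "RP",     22.5,     1.935,       -0.6,  "pulse",
    "TUB",    29.6,     1.914,        3.3,  "ramp",
    "UBQ",    19.6,     2.097,        0.5,  "pulse")
  gois <- tibble::tribble(
    ~gene,        ~mean_cq, ~efficiency, ~amplitude_log2, ~shape,
    "PeCOBL4",    27.0,     1.887,        3.0,            "pulse",
    "PeFLA12-1",  28.0,     1.944,        2.5,            "ramp",
    "PeFLA12-2",  28.5,     2.031,        2.0,            "ramp",
    "PeFLA12-3",  29.0,     2.074,        3.5,            "pulse",
    "PeFLA12-4",  28.0,     2.049,        2.8,            "ramp",
    "PeHKT1",     30.0,     2.054,        3.0,            "pulse",
    "PeKUP3",     29.5,     1.978,        2.0,            "ramp",
    "PeNhaD1",    28.5,     1.954,        2.5,            "ramp",
    "PeNHX2",     30.5,     2.062,        5.0,            "pulse")
  simulate_cq(sim_config(genes, gois, seed = seed))
}
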