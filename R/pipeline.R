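#' Workflow commands
#'
#' The `cmd_*` functions chain the package's stages into the standard
#' reference-gene evaluation workflow, reading and writing the CSV dialects
#' of [read_cq_table()] / [write_table()]. Multi-tissue inputs are looped
#' over tissue by tissue (each stability analysis is single-cohort). Every
#' output carries provenance comment headers (`# ...`) with the package
#' version, the command and the seed, and identical inputs plus seed give
#' byte-identical outputs. They back the `refstab` command-line script
#' (`exec/refstab`) but are equally usable from R.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic step.
#' @param config Optional YAML simulation configuration (see the vignette);
#'   by default the built-in salt time-course panel is simulated.
#' @param cq Path to a long-format Cq table.
#' @param efficiencies Optional path to a `gene,efficiency` table.
#' @param method One of `"dct"`, `"normfinder"`, `"genorm"`, `"graynorm"`,
#'   `"all"`.
#' @param groups NormFinder grouping variable (`"bio_rep"` or
#'   `"condition"`).
#' @param control Control condition label (needed by GrayNorm and
#'   normalization).
#' @param threshold,min_genes geNorm V threshold and minimum gene count.
#' @param inputs Character vector (or comma-separated string) of
#'   `stability_ranking` CSV paths to aggregate.
#' @param out Output file path.
#' @param gois Character vector (or comma-separated string) of genes of
#'   interest.
#' @param strategies Path to a YAML file mapping strategy names to gene
#'   lists (or the string `none`); a `none` strategy is always added.
#' @param max_size Largest GrayNorm combination size (default: all genes).
#' @return Invisibly, the paths written.
#' @name pipeline
NULL

.provenance <- function(cmd, seed = NULL) {
  c(paste0("refstab ", as.character(utils::packageVersion("refstab"))),
    paste0("command: ", cmd),
    if (!is.null(seed)) paste0("seed: ", seed))
}

.out_path <- function(out_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  file.path(out_dir, sprintf(...))
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(out_dir, seed = 1, config = NULL) {
  cfg <- if (is.null(config)) NULL else .sim_config_from_yaml(config, seed)
  sim <- if (is.null(cfg)) sim_salt_timecourse(seed = seed) else simulate_cq(cfg)
  hdr <- .provenance("simulate", seed)
  paths <- c(
    write_table(sim$dataset, .out_path(out_dir, "cq_data.csv"),
                header_lines = hdr),
    write_table(tibble::as_tibble(sim$efficiencies),
                .out_path(out_dir, "efficiencies.csv"), header_lines = hdr),
    write_table(sim$truth$genes, .out_path(out_dir, "truth_genes.csv"),
                header_lines = hdr))
  if (!is.null(sim$truth$goi_log2fc)) {
    paths <- c(paths, write_table(sim$truth$goi_log2fc,
                                  .out_path(out_dir, "truth_goi.csv"),
                                  header_lines = hdr))
  }
  message("simulate: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

.sim_config_from_yaml <- function(path, seed) {
  y <- yaml::read_yaml(path)
  genes <- dplyr::bind_rows(lapply(y$genes, tibble::as_tibble))
  gois <- if (!is.null(y$gois))
    dplyr::bind_rows(lapply(y$gois, tibble::as_tibble)) else NULL
  args <- list(genes = genes, gois = gois,
               seed = if (!is.null(y$seed)) y$seed else seed)
  for (k in c("tissues", "conditions", "n_bio", "n_tech", "sigma_b", "sigma_t")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(sim_config, args)
}

.load_inputs <- function(cq, efficiencies) {
  ds <- read_cq_table(cq, layout = "long")
  eff <- if (is.null(efficiencies)) NULL else read_efficiency_table(efficiencies)
  list(ds = ds, eff = eff)
}

#' @rdname pipeline
#' @export
cmd_summarize <- function(cq, out_dir, group_by = "tissue") {
  ds <- read_cq_table(cq, layout = "long")
  out <- summarize_cq(ds, group_by = group_by)
  p <- write_table(out, .out_path(out_dir, "cq_summary.csv"),
                   header_lines = .provenance("summarize"))
  invisible(p)
}

#' @rdname pipeline
#' @export
cmd_rank <- function(cq, efficiencies = NULL, method = "all", out_dir,
                     groups = "bio_rep", control = NULL,
                     threshold = 0.15, min_genes = 3) {
  methods <- if (method == "all") c("dct", "normfinder", "genorm",
                                    if (!is.null(control)) "graynorm")
             else method
  bad <- setdiff(methods, c("dct", "normfinder", "genorm", "graynorm"))
  if (length(bad) > 0) {
    stop("cmd_rank: unknown method(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inp <- .load_inputs(cq, efficiencies)
  paths <- character()
  for (tis in sort(unique(inp$ds$tissue))) {
    ds_t <- average_technical_replicates(filter_tissue(inp$ds, tis))
    for (m in methods) {
      hdr <- .provenance(paste("rank", m, tis))
      r <- switch(m,
        dct = as_ranking(pairwise_dct(ds_t)),
        normfinder = as_ranking(normfinder_stability(ds_t, inp$eff,
                                                     groups = groups)),
        genorm = {
          q <- to_quantities(ds_t, inp$eff)
          res <- genorm_rank(q)
          pv <- pairwise_variation(q, ranking_order(res))
          rec <- recommend_count(pv, threshold = threshold,
                                 min_genes = min_genes)
          paths <- c(paths,
            write_table(tibble::as_tibble(pv),
                        .out_path(out_dir, "pv_%s.csv", tis),
                        header_lines = hdr),
            write_table(tibble::tibble(n = rec$n, rule = rec$rule),
                        .out_path(out_dir, "genorm_recommendation_%s.csv", tis),
                        header_lines = hdr))
          as_ranking(res)
        },
        graynorm = {
          if (is.null(control)) {
            stop("cmd_rank: graynorm needs --control", call. = FALSE)
          }
          graynorm_gene_ranking(
            graynorm_rank_all(ds_t, inp$eff, control, max_size = 1))
        })
      paths <- c(paths, write_table(r, .out_path(out_dir, "rank_%s_%s.csv",
                                                 m, tis),
                                    header_lines = hdr))
    }
  }
  message("rank: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_aggregate <- function(inputs, out, seed = 1) {
  if (length(inputs) == 1) inputs <- strsplit(inputs, ",", fixed = TRUE)[[1]]
  if (length(inputs) < 1) stop("cmd_aggregate: no input rankings", call. = FALSE)
  lists <- lapply(inputs, function(p) {
    r <- .read_delim(p)
    if (!all(c("gene", "rank") %in% names(r))) {
      stop("cmd_aggregate: '", p, "' is not a ranking table (gene, rank)",
           call. = FALSE)
    }
    r$gene[order(as.numeric(r$rank))]
  })
  res <- aggregate_ce(lists, seed = seed)
  hdr <- c(.provenance("aggregate", seed),
           paste0("objective: ", res$objective),
           paste0("inputs: ", paste(basename(inputs), collapse = ", ")))
  dir <- dirname(out)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(tibble::tibble(rank = seq_along(res$consensus),
                             gene = res$consensus),
              out, header_lines = hdr)
  message("aggregate: consensus objective ", res$objective)
  invisible(out)
}

#' @rdname pipeline
#' @export
cmd_graynorm <- function(cq, efficiencies = NULL, control, out_dir,
                         min_genes = 3, max_size = NULL) {
  inp <- .load_inputs(cq, efficiencies)
  paths <- character()
  for (tis in sort(unique(inp$ds$tissue))) {
    ds_t <- average_technical_replicates(filter_tissue(inp$ds, tis))
    ranked <- graynorm_rank_all(ds_t, inp$eff, control, max_size = max_size)
    sel <- select_combination(ranked, min_genes = min_genes)
    hdr <- c(.provenance(paste("graynorm", tis)),
             paste0("control: ", control),
             paste0("selected: ", paste(sel, collapse = ";")))
    paths <- c(paths,
      write_table(tibble::as_tibble(ranked),
                  .out_path(out_dir, "graynorm_combinations_%s.csv", tis),
                  header_lines = hdr),
      write_table(tibble::tibble(gene = as.character(sel)),
                  .out_path(out_dir, "graynorm_selected_%s.csv", tis),
                  header_lines = hdr))
  }
  message("graynorm: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_normalize <- function(cq, efficiencies = NULL, control, gois,
                          strategies = NULL, out_dir) {
  if (length(gois) == 1) gois <- strsplit(gois, ",", fixed = TRUE)[[1]]
  strat <- list(none = "none")
  if (!is.null(strategies)) {
    y <- yaml::read_yaml(strategies)
    for (nm in names(y)) {
      strat[[nm]] <- if (identical(y[[nm]], "none")) "none"
                     else as.character(unlist(y[[nm]]))
    }
  }
  inp <- .load_inputs(cq, efficiencies)
  paths <- character()
  for (tis in sort(unique(inp$ds$tissue))) {
    ds_t <- average_technical_replicates(filter_tissue(inp$ds, tis))
    cmp <- compare_strategies(ds_t, inp$eff, gois, strat, control)
    hdr <- c(.provenance(paste("normalize", tis)),
             paste0("control: ", control))
    paths <- c(paths,
      write_table(cmp$profiles, .out_path(out_dir, "expression_%s.csv", tis),
                  header_lines = hdr),
      write_table(cmp$summary,
                  .out_path(out_dir, "strategy_summary_%s.csv", tis),
                  header_lines = hdr))
  }
  message("normalize: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' Command-line entry point
#'
#' Dispatches `refstab <subcommand> --flag value ...` to the corresponding
#' `cmd_*` function. Subcommands: `simulate`, `summarize`, `rank`,
#' `aggregate`, `graynorm`, `normalize`. Flags map one-to-one onto the
#' `cmd_*` arguments (e.g. `--cq`, `--efficiencies`, `--method`,
#' `--control`, `--out-dir`, `--seed`). Run without arguments for usage.
#'
#' @param argv Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, `0L` on success (errors propagate as R conditions;
#'   the shell script translates them into a non-zero exit status).
#' @export
refstab_main <- function(argv) {
  usage <- paste(
    "usage: refstab <command> [--flag value ...]",
    "commands:",
    "  simulate   --out-dir D [--seed N] [--config file.yaml]",
    "  summarize  --cq F --out-dir D [--group-by tissue|all]",
    "  rank       --cq F --out-dir D [--efficiencies F] [--method m]",
    "             [--groups bio_rep|condition] [--control C]",
    "             [--threshold X] [--min-genes N]",
    "  aggregate  --inputs f1,f2,... --out F [--seed N]",
    "  graynorm   --cq F --control C --out-dir D [--efficiencies F]",
    "             [--min-genes N] [--max-size N]",
    "  normalize  --cq F --control C --gois g1,g2 --out-dir D",
    "             [--efficiencies F] [--strategies file.yaml]",
    sep = "\n")
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- .parse_flags(argv[-1])
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  switch(cmd,
    simulate = cmd_simulate(out_dir = .req(opts, "out-dir"),
                            seed = num(opts[["seed"]]) %||% 1,
                            config = opts[["config"]]),
    summarize = cmd_summarize(cq = .req(opts, "cq"),
                              out_dir = .req(opts, "out-dir"),
                              group_by = opts[["group-by"]] %||% "tissue"),
    rank = cmd_rank(cq = .req(opts, "cq"),
                    efficiencies = opts[["efficiencies"]],
                    method = opts[["method"]] %||% "all",
                    out_dir = .req(opts, "out-dir"),
                    groups = opts[["groups"]] %||% "bio_rep",
                    control = opts[["control"]],
                    threshold = num(opts[["threshold"]]) %||% 0.15,
                    min_genes = num(opts[["min-genes"]]) %||% 3),
    aggregate = cmd_aggregate(inputs = .req(opts, "inputs"),
                              out = .req(opts, "out"),
                              seed = num(opts[["seed"]]) %||% 1),
    graynorm = cmd_graynorm(cq = .req(opts, "cq"),
                            efficiencies = opts[["efficiencies"]],
                            control = .req(opts, "control"),
                            out_dir = .req(opts, "out-dir"),
                            min_genes = num(opts[["min-genes"]]) %||% 3,
                            max_size = num(opts[["max-size"]])),
    normalize = cmd_normalize(cq = .req(opts, "cq"),
                              efficiencies = opts[["efficiencies"]],
                              control = .req(opts, "control"),
                              gois = .req(opts, "gois"),
                              strategies = opts[["strategies"]],
                              out_dir = .req(opts, "out-dir")),
    stop("refstab: unknown command '", cmd, "'\n", usage, call. = FALSE))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("refstab: unexpected argument '", a, "' (flags are --name value)",
           call. = FALSE)
    }
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      stop("refstab: flag '", a, "' needs a value", call. = FALSE)
    }
    opts[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

.req <- function(opts, name) {
  if (is.null(opts[[name]])) {
    stop("refstab: missing required flag --", name, call. = FALSE)
  }
  opts[[name]]
}
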