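#' Spearman footrule distance between two orderings
#'
#' Sum over items of the absolute difference between their (1-based)
#' positions in the two orderings. Both orderings must be full permutations
#' of the same item set.
#'
#' @param a,b Character (or atomic) vectors: complete orderings of the same
#'   items.
#' @return Non-negative integer distance.
#' @export
spearman_footrule <- function(a, b) {
  if (length(a) != length(b) || anyDuplicated(a) || anyDuplicated(b) ||
      !setequal(a, b)) {
    stop("spearman_footrule: orderings must be permutations of the same ",
         "item set", call. = FALSE)
  }
  sum(abs(seq_along(a) - match(a, b)))
}

.check_lists <- function(lists, weights) {
  if (!is.list(lists) || length(lists) < 1) {
    stop("need a non-empty list of rankings", call. = FALSE)
  }
  items <- sort(lists[[1]])
  for (l in lists) {
    if (anyDuplicated(l) || !identical(sort(l), items)) {
      stop("all ranked lists must be full permutations of the same item set",
           call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(lists))
  if (length(weights) != length(lists) || any(weights <= 0)) {
    stop("weights must be positive, one per list", call. = FALSE)
  }
  list(items = items, weights = weights)
}

# Weighted total footrule of candidate position matrix posC (N x G, item
# positions in sorted-item order) against the input lists.
.total_footrule <- function(posC, list_pos, weights) {
  obj <- numeric(nrow(posC))
  for (l in seq_along(list_pos)) {
    obj <- obj + weights[l] *
      rowSums(abs(posC - matrix(list_pos[[l]], nrow(posC), ncol(posC),
                                byrow = TRUE)))
  }
  obj
}

#' Consensus ranking by Cross-Entropy Monte-Carlo optimization
#'
#' Finds an ordering minimizing the (weighted) sum of Spearman footrule
#' distances to the input rankings. The sampler keeps an item-by-position
#' probability matrix, initially uniform; each iteration draws `N`
#' permutations by sequential sampling without replacement proportional to
#' the matrix columns, scores them, and moves the matrix toward the
#' empirical position frequencies of the elite fraction `rho`, retaining a
#' fraction `smoothing` of the previous matrix
#' (`p <- (1 - smoothing) * freq + smoothing * p`). The search stops when
#' the best objective has not improved for `patience` iterations, or after
#' `max_iter` iterations; the best permutation ever sampled is returned.
#'
#' @param lists List of k full orderings (character vectors) over one item
#'   set, best item first.
#' @param weights Optional positive per-list importance weights (default
#'   equal).
#' @param N Permutations sampled per iteration; default
#'   `max(100, 10 * G^2)` for G items.
#' @param rho Elite fraction (default 0.1); `ceiling(rho * N)` must be >= 1.
#' @param smoothing Fraction of the previous probability matrix retained at
#'   each update (default 0.25).
#' @param max_iter,patience Stopping controls (defaults 200 and 15).
#' @param seed Optional integer seed; given a seed the result is fully
#'   reproducible.
#' @return An object of class `rank_aggregation`: list with `consensus`
#'   (ordering, best first), `objective` (its weighted total footrule,
#'   exactly recomputable), `trace` (best objective after each iteration),
#'   `method = "CE"`, `params`, and `seed`.
#' @export
aggregate_ce <- function(lists, weights = NULL, N = NULL, rho = 0.1,
                         smoothing = 0.25, max_iter = 200, patience = 15,
                         seed = NULL) {
  chk <- .check_lists(lists, weights)
  items <- chk$items
  weights <- chk$weights
  G <- length(items)
  if (is.null(N)) N <- max(100, 10 * G^2)
  if (N < 10) stop("aggregate_ce: N must be at least 10", call. = FALSE)
  n_elite <- ceiling(rho * N)
  if (n_elite < 1) stop("aggregate_ce: rho * N must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (G == 1) {
    return(structure(list(consensus = items, objective = 0, trace = 0,
                          method = "CE",
                          params = list(N = N, rho = rho, smoothing = smoothing,
                                        max_iter = max_iter, patience = patience),
                          seed = seed),
                     class = "rank_aggregation"))
  }
  list_pos <- lapply(lists, function(l) match(items, l))

  p <- matrix(1 / G, G, G)            # p[item, position]
  UT <- upper.tri(matrix(0, G, G), diag = TRUE) * 1
  best_obj <- Inf
  best_perm <- NULL
  trace <- numeric(0)
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    P <- matrix(0L, N, G)             # sampled item index per position
    avail <- matrix(TRUE, N, G)
    for (j in seq_len(G)) {
      W <- avail * matrix(p[, j], N, G, byrow = TRUE)
      rs <- rowSums(W)
      fallback <- rs <= 0
      if (any(fallback)) {            # degenerate column: uniform on available
        W[fallback, ] <- avail[fallback, , drop = FALSE] * 1
        rs[fallback] <- rowSums(avail[fallback, , drop = FALSE])
      }
      cum <- W %*% UT
      u <- stats::runif(N) * rs
      pick <- max.col(cum >= u, ties.method = "first")
      P[, j] <- pick
      avail[cbind(seq_len(N), pick)] <- FALSE
    }
    posC <- matrix(0L, N, G)
    posC[cbind(rep(seq_len(N), G), as.vector(P))] <- rep(seq_len(G), each = N)
    obj <- .total_footrule(posC, list_pos, weights)
    it_best <- which.min(obj)
    if (obj[it_best] < best_obj) {
      best_obj <- obj[it_best]
      best_perm <- P[it_best, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best_obj)
    elite <- order(obj)[seq_len(n_elite)]
    f <- matrix(0, G, G)
    for (j in seq_len(G)) {
      f[, j] <- tabulate(P[elite, j], nbins = G) / n_elite
    }
    p <- (1 - smoothing) * f + smoothing * p
    if (stall >= patience) break
  }
  structure(list(consensus = items[best_perm],
                 objective = best_obj,
                 trace = trace,
                 method = "CE",
                 params = list(N = N, rho = rho, smoothing = smoothing,
                               max_iter = max_iter, patience = patience),
                 seed = seed),
            class = "rank_aggregation")
}

#' Exact consensus ranking by exhaustive enumeration
#'
#' Enumerates every permutation of the item set (factorial guard at 9
#' items) and returns the lexicographically smallest ordering attaining the
#' minimal weighted total footrule. Intended as the exact reference for
#' validating [aggregate_ce()] on small instances.
#'
#' @param lists,weights As in [aggregate_ce()].
#' @return A `rank_aggregation` object (`method = "exhaustive"`) with the
#'   extra field `n_optimal`, the number of co-optimal permutations.
#' @export
aggregate_exhaustive <- function(lists, weights = NULL) {
  chk <- .check_lists(lists, weights)
  items <- chk$items
  weights <- chk$weights
  G <- length(items)
  if (G > 9) {
    stop("aggregate_exhaustive: refusing ", G,
         "! permutations; use aggregate_ce() above 9 items", call. = FALSE)
  }
  list_pos <- lapply(lists, function(l) match(items, l))
  perms <- .permutations(G)           # lexicographic order of item indices
  posC <- matrix(0L, nrow(perms), G)
  posC[cbind(rep(seq_len(nrow(perms)), G), as.vector(perms))] <-
    rep(seq_len(G), each = nrow(perms))
  obj <- .total_footrule(posC, list_pos, weights)
  best <- min(obj)
  idx <- which(obj == best)[1]        # first = lexicographically smallest
  structure(list(consensus = items[perms[idx, ]],
                 objective = best,
                 trace = best,
                 method = "exhaustive",
                 n_optimal = sum(obj == best),
                 seed = NULL),
            class = "rank_aggregation")
}

# All permutations of 1..n as rows, in lexicographic order.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(first, block)
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.rank_aggregation <- function(x, ...) {
  cat(sprintf("<rank_aggregation> %s consensus (objective %g):\n  %s\n",
              x$method, x$objective, paste(x$consensus, collapse = " > ")))
  invisible(x)
}
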