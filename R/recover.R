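#' Recover an edge partition from a topological index vector
#'
#' Inverts the index computation: given the 11 index values of an unknown
#' molecular graph with maximum degree `max_degree`, finds the nonnegative
#' integer edge-partition counts that match the four integer-valued indices
#' `M1`, `M2`, `HM`, `F` exactly and minimise the squared deviation over the
#' remaining seven indices. The published tables print index values but not
#' the underlying graphs, so this is the auditable route from a printed index
#' row back to a degree structure.
#'
#' The search enumerates, by compiled branch-and-bound, every count vector
#' that consumes the `M1`, `M2` and `F` budgets exactly (`HM` is implied by
#' the identity `HM = F + 2*M2`, which is checked first), then scores each
#' candidate by the residual `sum((computed - target)^2)` over
#' `H, ABC, R, SC, GA, SO, N`. Ties on the residual are broken by
#' lexicographically smallest count vector, and uniqueness of the optimum is
#' reported. The 11 per-edge weight vectors are linearly independent over the
#' rationals, so an index vector computed exactly from a real graph recovers
#' that graph's partition uniquely with residual 0.
#'
#' @param iv named numeric vector with all of [index_ids()].
#' @param max_degree maximum endpoint degree to consider (`<= 4` covers the
#'   chemistry convention; 10 candidate degree pairs).
#' @param max_solutions,max_nodes search safety caps; exceeding either aborts
#'   with an error rather than returning a possibly non-optimal partition.
#' @return An [edge_partition()] with attributes `residual` (squared deviation
#'   over the seven non-integer indices), `unique` (logical: single optimum
#'   up to the residual tie tolerance of 1e-9) and `n_candidates` (number of
#'   count vectors matching the integer indices).
#' @section Infeasibility: if `HM != F + 2*M2` on the rounded integer values,
#'   or no nonnegative integer count vector matches them, an error of class
#'   `topoqspr_infeasible` is signalled; its condition object carries the best
#'   achievable residual (and best partition) over count vectors matching
#'   `M1`, `M2`, `F`, when any exist.
#' @examples
#' p <- recover_partition(compute_all(diclofenac_partition()))
#' attr(p, "residual")
#' @export
recover_partition <- function(iv, max_degree = 4L,
                              max_solutions = 2e6, max_nodes = 5e8) {
  stopifnot(is.numeric(iv), all(index_ids() %in% names(iv)))
  iv <- iv[index_ids()]
  max_degree <- as.integer(max_degree)
  if (max_degree < 1L) stop("max_degree must be >= 1")
  hard <- c("M1", "M2", "HM", "F")
  ih <- round(iv[hard])
  if (any(abs(iv[hard] - ih) > 1e-6))
    stop("M1, M2, HM and F must be integer-valued; got ",
         paste(sprintf("%s=%g", hard, iv[hard]), collapse = ", "))

  pairs <- do.call(rbind, lapply(seq_len(max_degree), function(a)
    cbind(a = a, b = a:max_degree)))
  pairs <- pairs[order(-(pairs[, 1]^2 + pairs[, 2]^2)), , drop = FALSE]
  identity_gap <- ih[["HM"]] - ih[["F"]] - 2 * ih[["M2"]]
  if (identity_gap != 0) {
    # doomed to the infeasibility error; bound the effort spent on the
    # best-residual report
    max_solutions <- min(max_solutions, 2e5)
    max_nodes <- min(max_nodes, 2e7)
  }
  enum <- .cpp_enumerate_partitions(pairs, ih[["M1"]], ih[["M2"]], ih[["F"]],
                                    max_solutions, max_nodes)
  if (enum$truncated && identity_gap == 0)
    stop("partition search exceeded its safety caps (", enum$nodes,
         " nodes); raise max_solutions/max_nodes")
  sols <- enum$solutions

  soft <- setdiff(index_ids(), hard)
  softW <- suppressWarnings(
    vapply(soft, function(id) edge_contribution(id, pairs[, 1], pairs[, 2]),
           numeric(nrow(pairs))))
  residuals <- if (nrow(sols)) {
    dev <- sols %*% softW - rep(iv[soft], each = nrow(sols))
    rowSums(dev^2)
  } else numeric(0)

  canonical <- order(pairs[, 1], pairs[, 2])
  build <- function(counts) {
    p <- as_edge_partition(data.frame(a = pairs[, 1], b = pairs[, 2],
                                      count = counts)[canonical, ])
    p
  }

  if (identity_gap != 0 || !nrow(sols)) {
    best <- if (nrow(sols)) min(residuals) else NA_real_
    cond <- structure(
      class = c("topoqspr_infeasible", "error", "condition"),
      list(message = paste0(
             "no nonnegative integer edge partition matches the integer indices",
             if (identity_gap != 0)
               sprintf(" (identity violated: HM - F - 2*M2 = %d)", identity_gap),
             if (!is.na(best))
               sprintf("; best residual over the remaining indices = %.6g", best)),
           call = sys.call(),
           residual = best,
           identity_gap = identity_gap,
           best_partition = if (nrow(sols))
             build(sols[which.min(residuals), ]) else NULL))
    stop(cond)
  }

  tol <- 1e-9 * max(1, min(residuals))
  opt <- which(residuals <= min(residuals) + tol)
  if (length(opt) > 1L) {
    # lexicographic tie-break on the canonical (a, b)-ordered count vector
    lex <- sols[opt, canonical, drop = FALSE]
    o <- do.call(order, as.data.frame(lex))
    opt <- opt[o]
  }
  p <- build(sols[opt[1L], ])
  attr(p, "residual") <- residuals[opt[1L]]
  attr(p, "unique") <- length(opt) == 1L
  attr(p, "n_candidates") <- nrow(sols)
  p
}
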