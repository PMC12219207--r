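#' Molecular graphs as hydrogen-suppressed simple graphs
#'
#' A molecular graph records the heavy (non-hydrogen) atoms of a compound as
#' vertices and covalent bonds as edges, ignoring bond order. All degree-based
#' topological indices of this package depend on the graph only through its
#' vertex degrees, so the class stores the edge set and derives degrees from it.
#'
#' @param edges two-column integer matrix of 0-based vertex ids, one edge per
#'   row. Self-loops and duplicate edges (in either orientation) are rejected.
#' @param n_vertices number of vertices. Defaults to `max(edges) + 1`; may be
#'   larger, but isolated vertices violate the degree >= 1 invariant and are
#'   rejected.
#' @param chemistry if `TRUE` (default) enforce the chemistry convention that
#'   no atom exceeds degree 4.
#'
#' @return An object of class `molecular_graph`: a list with elements
#'   `edges` (sorted two-column matrix), `n_vertices`, `degrees` (integer
#'   vector indexed by vertex id + 1), and `connected` (logical).
#'
#' @details Connectivity is checked and reported via the `connected` field and
#'   a warning, not an error: every index formula is a sum of per-edge terms
#'   and remains well defined on a disconnected graph.
#'
#' @examples
#' g <- molecular_graph(rbind(c(0, 1), c(1, 2)))
#' degrees(g)
#' @export
molecular_graph <- function(edges, n_vertices = NULL, chemistry = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0L) stop("graph must have at least one edge")
  if (any(edges < 0L)) stop("vertex ids must be nonnegative (0-based)")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  # canonical orientation u < v, then sort rows for determinism
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  nv <- max(edges) + 1L
  if (!is.null(n_vertices)) {
    n_vertices <- as.integer(n_vertices)
    if (n_vertices < nv) stop("n_vertices smaller than largest vertex id + 1")
    nv <- n_vertices
  }
  deg <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = nv)
  if (any(deg == 0L))
    stop("every vertex must have degree >= 1 (isolated vertex ids: ",
         paste(which(deg == 0L) - 1L, collapse = ", "), ")")
  if (chemistry && max(deg) > 4L)
    stop("maximum degree ", max(deg), " exceeds the chemistry bound of 4")
  g <- structure(
    list(edges = unname(edges), n_vertices = nv, degrees = deg,
         connected = is_connected_graph(edges, nv)),
    class = "molecular_graph")
  if (!g$connected) warning("molecular graph is not connected")
  g
}

# breadth-first reachability on the edge list
is_connected_graph <- function(edges, nv) {
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1] + 1L; v <- edges[i, 2] + 1L
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nbr <- adj[[u]]
    new <- nbr[!seen[nbr]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", x$n_vertices, "vertices,", nrow(x$edges), "edges,",
      if (x$connected) "connected" else "NOT connected", "\n")
  cat("degree sequence:", paste(sort(x$degrees, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Vertex degrees of a molecular graph
#'
#' @param g a `molecular_graph`.
#' @return Integer vector of degrees, element `i` for vertex id `i - 1`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  g$degrees
}

#' Parse an edge-list text into a molecular graph
#'
#' The edge-list dialect is one edge per line: two whitespace-separated
#' 0-based integer vertex ids. Lines starting with `#` (and blank lines) are
#' comments. Parse errors report the offending line number.
#'
#' @param text character scalar or vector of lines; ignored if `file` given.
#' @param file path to an edge-list file.
#' @inheritParams molecular_graph
#' @return A [molecular_graph()].
#' @examples
#' graph_from_edge_list("0 1\n1 2")
#' @export
graph_from_edge_list <- function(text = NULL, file = NULL, chemistry = TRUE) {
  lines <- if (!is.null(file)) readLines(file) else
    unlist(strsplit(as.character(text), "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("edge list contains no edges")
  parse_line <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L)
      stop("line ", i, ": expected two vertex ids, got '", lines[i], "'")
    if (!all(grepl("^[0-9]+$", tok)))
      stop("line ", i, ": non-integer vertex id in '", lines[i], "'")
    u <- as.integer(tok)
    if (u[1] == u[2]) stop("line ", i, ": self-loop '", lines[i], "'")
    u
  }
  em <- t(vapply(idx, parse_line, integer(2)))
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  if (anyDuplicated(key))
    stop("line ", idx[which(duplicated(key))[1]], ": duplicate edge")
  molecular_graph(em, chemistry = chemistry)
}

#' Write a molecular graph in the edge-list dialect
#'
#' Emits edges sorted by (min id, max id) so output is deterministic.
#'
#' @param g a `molecular_graph`.
#' @param file path to write; with `file = ""` the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of lines.
#' @export
write_edge_list <- function(g, file = "") {
  stopifnot(inherits(g, "molecular_graph"))
  lines <- paste(g$edges[, 1], g$edges[, 2])
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

#' Edge partition of a molecular graph by endpoint degrees
#'
#' Groups the edges of `g` by the unordered pair of endpoint degrees
#' `(a, b)`, `a <= b`. The partition is the sufficient statistic for every
#' degree-based topological index: an index is a weighted sum of the counts.
#'
#' @param g a `molecular_graph`, or a data frame with columns `a`, `b`,
#'   `count` to be validated and classed.
#' @return An `edge_partition`: a data frame with integer columns `a`, `b`
#'   (degrees, `a <= b`) and `count`, ordered by `(a, b)`, carrying the total
#'   edge count as attribute `n_edges`.
#' @examples
#' g <- graph_from_edge_list("0 1\n1 2\n2 3\n3 0") # 4-cycle
#' edge_partition(g)
#' @export
edge_partition <- function(g) {
  if (is.data.frame(g)) return(as_edge_partition(g))
  stopifnot(inherits(g, "molecular_graph"))
  d <- g$degrees
  du <- d[g$edges[, 1] + 1L]
  dv <- d[g$edges[, 2] + 1L]
  a <- pmin(du, dv); b <- pmax(du, dv)
  tab <- stats::aggregate(list(count = a), by = list(a = a, b = b), FUN = length)
  as_edge_partition(tab)
}

#' @rdname edge_partition
#' @param x data frame with columns `a`, `b`, `count`.
#' @export
as_edge_partition <- function(x) {
  stopifnot(is.data.frame(x), all(c("a", "b", "count") %in% names(x)))
  x <- data.frame(a = as.integer(x$a), b = as.integer(x$b),
                  count = as.integer(x$count))
  if (any(x$a < 1L) || any(x$b < x$a)) stop("degree pairs must satisfy 1 <= a <= b")
  if (any(x$count < 0L)) stop("counts must be nonnegative")
  x <- x[x$count > 0L, , drop = FALSE]
  if (nrow(x) == 0L) stop("edge partition is empty")
  if (anyDuplicated(x[c("a", "b")])) stop("duplicate degree pair in partition")
  x <- x[order(x$a, x$b), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, n_edges = sum(x$count),
            class = c("edge_partition", "data.frame"))
}

#' @export
as.data.frame.edge_partition <- function(x, ...) {
  data.frame(a = x$a, b = x$b, count = x$count)
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("edge_partition:", attr(x, "n_edges"), "edges\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total edge count of an edge partition
#' @param p an `edge_partition`.
#' @return Integer edge count.
#' @export
n_edges <- function(p) {
  stopifnot(inherits(p, "edge_partition"))
  attr(p, "n_edges")
}
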