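#' The eleven degree-based topological indices
#'
#' Every index supported here is a sum over the edges `uv` of a molecular
#' graph of a term depending only on the endpoint degrees `a = d_u`,
#' `b = d_v`:
#'
#' | id  | name                    | per-edge term                |
#' |-----|-------------------------|------------------------------|
#' | M1  | first Zagreb            | `a + b`                      |
#' | M2  | second Zagreb           | `a * b`                      |
#' | H   | harmonic                | `2 / (a + b)`                |
#' | HM  | hyper-Zagreb            | `(a + b)^2`                  |
#' | F   | forgotten               | `a^2 + b^2`                  |
#' | ABC | atom-bond connectivity  | `sqrt((a + b - 2) / (a * b))`|
#' | R   | Randic                  | `1 / sqrt(a * b)`            |
#' | SC  | sum-connectivity        | `1 / sqrt(a + b)`            |
#' | GA  | geometric-arithmetic    | `2 * sqrt(a * b) / (a + b)`  |
#' | SO  | Sombor                  | `sqrt(a^2 + b^2)`            |
#' | N   | Nirmala                 | `sqrt(a + b)`                |
#'
#' The identity `HM = F + 2 * M2` holds for every graph and is used throughout
#' the package to validate data.
#'
#' @return `index_ids()` returns the fixed character vector of the 11 index
#'   identifiers, in table order.
#' @export
index_ids <- function() {
  c("M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "SO", "N")
}

#' Per-edge contribution of a degree-based index
#'
#' @param index_id one of [index_ids()].
#' @param a,b endpoint degrees, integers `>= 1` (vectorised).
#' @return Numeric vector of per-edge terms.
#' @details The ABC term at an `(1, 1)` edge (an isolated K2 component) is the
#'   limit value 0; it is returned with a warning rather than an error, since
#'   the formula's numerator vanishes there.
#' @examples
#' edge_contribution("M1", 2, 3) # 5
#' edge_contribution("GA", 2, 2) # 1
#' @export
edge_contribution <- function(index_id, a, b) {
  if (length(index_id) != 1L || !index_id %in% index_ids())
    stop("unknown index id '", paste(index_id, collapse = ","),
         "'; valid ids: ", paste(index_ids(), collapse = ", "))
  if (any(a < 1) || any(b < 1)) stop("degrees must be >= 1")
  a <- as.numeric(a); b <- as.numeric(b)
  if (index_id == "ABC" && any(a == 1 & b == 1))
    warning("ABC contribution of a (1,1) edge taken as its limit value 0")
  switch(index_id,
    M1  = a + b,
    M2  = a * b,
    H   = 2 / (a + b),
    HM  = (a + b)^2,
    F   = a^2 + b^2,
    ABC = sqrt((a + b - 2) / (a * b)),
    R   = 1 / sqrt(a * b),
    SC  = 1 / sqrt(a + b),
    GA  = 2 * sqrt(a * b) / (a + b),
    SO  = sqrt(a^2 + b^2),
    N   = sqrt(a + b))
}

#' Compute one index from an edge partition
#'
#' @param p an [edge_partition()].
#' @param index_id one of [index_ids()].
#' @return The index value: `sum(count * edge_contribution(index_id, a, b))`.
#' @examples
#' compute_index(diclofenac_partition(), "M1") # 94
#' @export
compute_index <- function(p, index_id) {
  p <- if (inherits(p, "edge_partition")) p else as_edge_partition(p)
  sum(p$count * edge_contribution(index_id, p$a, p$b))
}

#' Compute all eleven indices from an edge partition
#'
#' @param p an [edge_partition()] (or a `molecular_graph`, which is
#'   partitioned first).
#' @return Named numeric vector over [index_ids()].
#' @examples
#' round(compute_all(diclofenac_partition()), 3)
#' @export
compute_all <- function(p) {
  if (inherits(p, "molecular_graph")) p <- edge_partition(p)
  iv <- vapply(index_ids(), compute_index, numeric(1), p = p)
  stopifnot(abs(iv["HM"] - iv["F"] - 2 * iv["M2"]) <= 1e-9 * max(1, iv["HM"]))
  iv
}

#' Batch index computation for a set of graphs or partitions
#'
#' Computes the full index table for either a directory of edge-list files
#' (one compound per file, compound named after the file) or a long-format
#' partition data frame with columns `drug`, `a`, `b`, `count`.
#'
#' @param x directory path, or data frame with columns `drug`, `a`, `b`,
#'   `count`, or a named list of `molecular_graph`/`edge_partition` objects.
#' @param file optional path; when given, the table is also written as CSV in
#'   the fixture schema (`drug` column plus the 11 index columns).
#' @return Data frame with column `drug` and one column per index id.
#' @export
compute_index_table <- function(x, file = NULL) {
  parts <- if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt edge-list files in ", x)
    stats::setNames(
      lapply(files, function(f) edge_partition(graph_from_edge_list(file = f))),
      sub("\\.txt$", "", basename(files)))
  } else if (is.data.frame(x)) {
    stopifnot(all(c("drug", "a", "b", "count") %in% names(x)))
    lapply(split(x[c("a", "b", "count")], x$drug), as_edge_partition)
  } else if (is.list(x)) {
    if (is.null(names(x))) stop("list input must be named by compound")
    lapply(x, function(g) if (inherits(g, "molecular_graph")) edge_partition(g) else
      as_edge_partition(g))
  } else stop("unsupported input for compute_index_table()")
  tab <- do.call(rbind, lapply(parts, function(p) as.data.frame(t(compute_all(p)))))
  tab <- cbind(drug = names(parts), tab)
  rownames(tab) <- NULL
  if (!is.null(file))
    utils::write.csv(tab, file, row.names = FALSE, quote = FALSE, na = "NA")
  tab
}
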