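# Run code under a local RNG stream so generators are pure functions of their
# seed and leave the caller's RNG state untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random connected molecular graph with bounded degree
#'
#' Builds a uniform-ish random connected simple graph the way a
#' hydrogen-suppressed molecule looks to the degree-based indices: a random
#' spanning tree grown by attaching each new vertex to a uniformly chosen
#' existing vertex with spare valence (guaranteeing connectivity without
#' rejection), followed by optional extra edges creating rings, each candidate
#' non-adjacent pair accepted independently with probability
#' `extra_edge_prob` if both endpoint degrees stay within `max_degree`.
#'
#' @param n_vertices number of vertices, `>= 2`.
#' @param max_degree maximum vertex degree (default 4, the carbon valence
#'   bound).
#' @param extra_edge_prob probability of accepting each candidate ring-closing
#'   edge (default 0.15, giving drug-like ring counts at 10-30 atoms).
#' @param seed integer seed; identical seeds give identical graphs.
#' @return A [molecular_graph()].
#' @examples
#' g <- random_molecular_graph(12, seed = 7)
#' max(degrees(g)) <= 4
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4L,
                                   extra_edge_prob = 0.15, seed) {
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 2L) stop("n_vertices must be >= 2")
  stopifnot(max_degree >= 1L, extra_edge_prob >= 0, extra_edge_prob <= 1)
  with_local_seed(seed, {
    deg <- integer(n_vertices)
    edges <- matrix(0L, 0L, 2L)
    for (v in 1L:(n_vertices - 1L)) {
      avail <- which(deg[1:v] < max_degree) - 1L
      if (!length(avail))
        stop("cannot grow a connected graph: max_degree too small")
      u <- if (length(avail) == 1L) avail else sample(avail, 1L)
      edges <- rbind(edges, c(u, v))
      deg[u + 1L] <- deg[u + 1L] + 1L
      deg[v + 1L] <- deg[v + 1L] + 1L
    }
    if (extra_edge_prob > 0 && n_vertices > 2L) {
      cand <- which(upper.tri(matrix(TRUE, n_vertices, n_vertices)), arr.ind = TRUE) - 1L
      have <- paste(edges[, 1], edges[, 2])
      cand <- cand[!paste(cand[, 1], cand[, 2]) %in% have, , drop = FALSE]
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        u <- cand[i, 1]; v <- cand[i, 2]
        if (deg[u + 1L] < max_degree && deg[v + 1L] < max_degree &&
            stats::runif(1) < extra_edge_prob) {
          edges <- rbind(edges, c(u, v))
          deg[u + 1L] <- deg[u + 1L] + 1L
          deg[v + 1L] <- deg[v + 1L] + 1L
        }
      }
    }
    molecular_graph(edges, n_vertices, chemistry = max_degree <= 4L)
  })
}

#' Configuration for a synthetic QSPR dataset
#'
#' @param n_compounds number of synthetic compounds.
#' @param intercept true intercept of the linear property-index relation.
#' @param coefficients named numeric vector of true coefficients over index
#'   ids (the chosen regressors).
#' @param sigma standard deviation of the additive Gaussian noise, `>= 0`.
#' @param n_vertices_range inclusive range of graph sizes to draw from.
#' @param seed integer seed.
#' @return A `synth_qspr_config` list.
#' @export
synth_qspr_config <- function(n_compounds = 50L, intercept = 10,
                              coefficients = c(M1 = 2, H = -5, SO = 0.5),
                              sigma = 1, n_vertices_range = c(10L, 30L),
                              seed = 1L) {
  stopifnot(sigma >= 0, n_compounds >= 1,
            all(names(coefficients) %in% index_ids()))
  structure(list(n_compounds = as.integer(n_compounds), intercept = intercept,
                 coefficients = coefficients, sigma = sigma,
                 n_vertices_range = as.integer(n_vertices_range),
                 seed = as.integer(seed)),
            class = "synth_qspr_config")
}

#' Generate a synthetic QSPR dataset with known truth
#'
#' Draws random bounded-degree connected graphs, computes their real index
#' table, and simulates the response as the configured linear combination of
#' the chosen indices plus `Normal(0, sigma^2)` noise — the data-generating
#' process the regression module assumes. The true parameters are returned so
#' recovery can be tested.
#'
#' @param cfg a [synth_qspr_config()].
#' @return List with `indices` (data frame: `drug` column plus all 11 index
#'   columns), `response` (numeric vector), `truth` (list with `intercept`,
#'   `coefficients`, `sigma`) and `graphs` (the generating graphs).
#' @export
synth_qspr_dataset <- function(cfg = synth_qspr_config()) {
  stopifnot(inherits(cfg, "synth_qspr_config"))
  with_local_seed(cfg$seed, {
    sizes <- sample(cfg$n_vertices_range[1]:cfg$n_vertices_range[2],
                    cfg$n_compounds, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max, cfg$n_compounds)
    noise <- stats::rnorm(cfg$n_compounds, 0, cfg$sigma)
    graphs <- lapply(seq_len(cfg$n_compounds), function(i)
      random_molecular_graph(sizes[i], seed = seeds[i]))
    names(graphs) <- sprintf("synth%03d", seq_along(graphs))
    it <- compute_index_table(graphs)
    X <- as.matrix(it[, names(cfg$coefficients), drop = FALSE])
    y <- cfg$intercept + drop(X %*% cfg$coefficients) + noise
    list(indices = it, response = y,
         truth = list(intercept = cfg$intercept,
                      coefficients = cfg$coefficients, sigma = cfg$sigma),
         graphs = graphs)
  })
}

#' Synthetic decision matrix with planted structure
#'
#' Uniform random positive cells, optionally with one planted dominant
#' alternative (every cell 1.1 times the column maximum of the others) and/or
#' one planted dominated alternative (0.9 times the column minimum) —
#' mirroring the dominance structure of the published ranking tables, where
#' one drug is best and one worst on every criterion.
#'
#' @param n_alt number of alternatives, `>= 2`.
#' @param n_crit number of criteria.
#' @param with_dominant,with_dominated plant the extreme alternatives
#'   (named `dominant` / `dominated`; the random ones are `alt...`).
#' @param seed integer seed.
#' @return A `decision_matrix`.
#' @export
synth_decision_matrix <- function(n_alt = 6L, n_crit = 4L,
                                  with_dominant = FALSE,
                                  with_dominated = FALSE, seed = 1L) {
  stopifnot(n_alt >= 2L, n_crit >= 1L)
  with_local_seed(seed, {
    n_rand <- n_alt - with_dominant - with_dominated
    if (n_rand < 1L) stop("n_alt too small for the planted alternatives")
    m <- matrix(stats::runif(n_rand * n_crit, 10, 100), n_rand, n_crit)
    rownames(m) <- sprintf("alt%02d", seq_len(n_rand))
    if (with_dominant)
      m <- rbind(m, dominant = apply(m, 2, max) * 1.1)
    if (with_dominated)
      m <- rbind(m, dominated = apply(m[seq_len(n_rand), , drop = FALSE], 2, min) * 0.9)
    colnames(m) <- sprintf("crit%02d", seq_len(n_crit))
    as_decision_matrix(m)
  })
}
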