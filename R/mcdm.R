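#' Build a decision matrix from the packaged tables
#'
#' Assembles the alternatives x criteria matrix for TOPSIS/VIKOR ranking from
#' either the property table (22 x 7) or the index table (22 x 11). All
#' criteria are treated as beneficial (larger is better), consistent with the
#' published ranking in which the drug maximal in every column ranks first.
#'
#' The property table has five missing cells, resolved by `missing_policy`:
#' \describe{
#'   \item{`predicted`}{substitute the published predicted value when one is
#'     printed, else fall back to the column mean. (The published
#'     predicted table omits exactly the cells missing from the property
#'     table, so in practice this falls back to the column mean; every
#'     substitution is logged.)}
#'   \item{`mean`}{substitute the column mean of the observed cells.}
#'   \item{`drop-criterion`}{drop any criterion column with a missing cell.}
#' }
#'
#' @param source `"properties"` or `"indices"`.
#' @param missing_policy `"predicted"`, `"mean"` or `"drop-criterion"`.
#' @param pt,it,predicted the underlying tables; default to the packaged
#'   fixtures.
#' @return A `decision_matrix`: numeric matrix with drug row names and
#'   criterion column names, attributes `direction` (per-criterion
#'   `"beneficial"`) and `substitutions` (log data frame with columns
#'   `drug`, `criterion`, `value`, `source`).
#' @export
build_decision_matrix <- function(source = c("properties", "indices"),
                                  missing_policy = c("predicted", "mean",
                                                     "drop-criterion"),
                                  pt = load_property_table(),
                                  it = load_index_table(),
                                  predicted = load_predicted_table()) {
  source <- match.arg(source)
  missing_policy <- match.arg(missing_policy)
  tab <- if (source == "properties") pt else it
  m <- as.matrix(tab[, setdiff(names(tab), "drug"), drop = FALSE])
  rownames(m) <- tab$drug
  subs <- data.frame(drug = character(), criterion = character(),
                     value = numeric(), source = character())
  if (anyNA(m)) {
    if (missing_policy == "drop-criterion") {
      m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
    } else {
      for (j in colnames(m)) {
        miss <- which(is.na(m[, j]))
        for (i in miss) {
          val <- NA_real_; src <- NA_character_
          if (missing_policy == "predicted" && j %in% names(predicted)) {
            val <- predicted[[j]][match(rownames(m)[i], predicted$drug)]
            src <- "predicted"
          }
          if (is.na(val)) {
            val <- mean(m[, j], na.rm = TRUE)
            src <- "column mean"
          }
          m[i, j] <- val
          subs <- rbind(subs, data.frame(drug = rownames(m)[i], criterion = j,
                                         value = val, source = src))
        }
      }
    }
  }
  if (anyNA(m)) stop("missing cells remain after policy '", missing_policy, "'")
  as_decision_matrix(m, substitutions = subs)
}

#' @rdname build_decision_matrix
#' @param m numeric matrix (alternatives x criteria) with row and column names.
#' @param substitutions optional substitution log.
#' @export
as_decision_matrix <- function(m, substitutions = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("decision matrix needs at least 2 alternatives")
  if (ncol(m) < 1L) stop("decision matrix needs at least 1 criterion")
  if (anyNA(m)) stop("decision matrix must be complete")
  if (any(colSums(m^2) == 0)) stop("criteria columns must have nonzero norm")
  if (is.null(rownames(m))) rownames(m) <- paste0("alt", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("crit", seq_len(ncol(m)))
  structure(m,
            direction = stats::setNames(rep("beneficial", ncol(m)), colnames(m)),
            substitutions = substitutions,
            class = c("decision_matrix", "matrix", "array"))
}

#' Criterion weight vectors
#'
#' `equal_weights(n)` gives each of `n` criteria weight `1/n`;
#' `ratio_weights(scores)` normalises nonnegative importance scores to sum to
#' one (the "ratio method").
#'
#' @param n_criteria number of criteria.
#' @param scores nonnegative numeric scores, e.g. absolute correlations.
#' @return Numeric weight vector summing to 1.
#' @export
equal_weights <- function(n_criteria) {
  stopifnot(n_criteria >= 1L)
  rep(1 / n_criteria, n_criteria)
}

#' @rdname equal_weights
#' @export
ratio_weights <- function(scores) {
  if (any(scores < 0)) stop("scores must be nonnegative")
  s <- sum(scores)
  if (s <= 0) stop("at least one score must be positive")
  scores / s
}

check_weights <- function(w, m) {
  if (length(w) != ncol(m))
    stop("weight vector length ", length(w), " != ", ncol(m), " criteria")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  w
}

#' TOPSIS ranking
#'
#' Technique for Order Preference by Similarity to Ideal Solution. Columns are
#' vector-normalised (`r_ij = x_ij / sqrt(sum_i x_ij^2)`), weighted, and each
#' alternative is scored by its relative closeness
#' `C_i = D_i^- / (D_i^+ + D_i^-)` to the ideal (per-criterion maximum, all
#' criteria beneficial) and anti-ideal (minimum) points, `D_i^+`/`D_i^-`
#' being Euclidean distances. Rank 1 is the largest `C_i`.
#'
#' @param D a `decision_matrix` (or plain matrix).
#' @param w weight vector over criteria (default equal weights).
#' @return A `topsis_result` data frame with columns `alternative`, `Dplus`,
#'   `Dminus`, `C`, `rank`, plus attributes `weighted` (the weighted
#'   normalised matrix), `ideal` and `anti_ideal`.
#' @details Ties in `C` are broken alphabetically by alternative name so ranks
#'   are deterministic and auditable.
#' @examples
#' D <- as_decision_matrix(rbind(a = c(10, 3), b = c(5, 1)))
#' topsis(D)
#' @export
topsis <- function(D, w = equal_weights(ncol(D))) {
  D <- if (inherits(D, "decision_matrix")) D else as_decision_matrix(D)
  w <- check_weights(w, D)
  norm <- sqrt(colSums(unclass(D)^2))
  v <- sweep(sweep(unclass(D), 2, norm, "/"), 2, w, "*")
  ideal <- apply(v, 2, max)
  anti <- apply(v, 2, min)
  if (all(ideal == anti))
    stop("all alternatives are identical; closeness is undefined")
  dplus <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  dminus <- sqrt(rowSums(sweep(v, 2, anti)^2))
  C <- dminus / (dplus + dminus)
  rk <- integer(length(C))
  rk[order(-C, rownames(D))] <- seq_along(C)
  res <- data.frame(alternative = rownames(D), Dplus = dplus, Dminus = dminus,
                    C = C, rank = rk, row.names = NULL)
  structure(res, weighted = v, ideal = ideal, anti_ideal = anti,
            class = c("topsis_result", "data.frame"))
}

#' VIKOR compromise ranking
#'
#' Scores each alternative by the group utility
#' `S_j = sum_i w_i (f_i^* - f_ij) / (f_i^* - f_i^-)`, the individual regret
#' `R_j = max_i` of the same terms, and the compromise score
#' `Q_j = v (S_j - S^*)/(S^- - S^*) + (1 - v) (R_j - R^*)/(R^- - R^*)`,
#' where `f_i^*`/`f_i^-` are the per-criterion best (maximum, beneficial) and
#' worst values and `*`/`-` superscripts denote minima/maxima over
#' alternatives. Rank 1 is the smallest `Q`.
#'
#' @param D a `decision_matrix` (or plain matrix).
#' @param w weight vector over criteria (default equal weights).
#' @param v trade-off between group utility and regret, in `[0, 1]`
#'   (default 0.5, the standard compromise).
#' @return A `vikor_result` data frame with columns `alternative`, `S`, `R`,
#'   `Q`, `rank`, plus attributes `f_best`, `f_worst`, `v`,
#'   `acceptable_advantage` and `acceptable_stability` (the standard
#'   compromise-solution conditions for the rank-1 alternative).
#' @details A criterion with `f_i^* = f_i^-` contributes 0 (its term is
#'   undefined); if all `S_j` tie, the `Q` terms are defined as 0 with a
#'   warning. Ties in `Q` are broken alphabetically.
#' @export
vikor <- function(D, w = equal_weights(ncol(D)), v = 0.5) {
  D <- if (inherits(D, "decision_matrix")) D else as_decision_matrix(D)
  w <- check_weights(w, D)
  stopifnot(v >= 0, v <= 1)
  X <- unclass(D)
  fb <- apply(X, 2, max)
  fw <- apply(X, 2, min)
  span <- fb - fw
  terms <- sweep(-sweep(X, 2, fb), 2, ifelse(span == 0, Inf, span), "/")
  terms <- sweep(terms, 2, w, "*")     # w_i (f* - f) / (f* - f-), 0 if span 0
  S <- rowSums(terms)
  R <- apply(terms, 1, max)
  qpart <- function(x) {
    if (max(x) == min(x)) {
      warning("all alternatives tie; Q term defined as 0")
      rep(0, length(x))
    } else (x - min(x)) / (max(x) - min(x))
  }
  Q <- v * qpart(S) + (1 - v) * qpart(R)
  rk <- integer(length(Q))
  rk[order(Q, rownames(X))] <- seq_along(Q)
  ord <- order(rk)
  m <- nrow(X)
  adv <- if (m > 2L)
    Q[ord[2L]] - Q[ord[1L]] >= 1 / (m - 1) else TRUE
  stab <- rk[which.min(S)] == 1L || rk[which.min(R)] == 1L
  res <- data.frame(alternative = rownames(X), S = S, R = R, Q = Q, rank = rk,
                    row.names = NULL)
  structure(res, f_best = fb, f_worst = fw, v = v,
            acceptable_advantage = adv, acceptable_stability = stab,
            class = c("vikor_result", "data.frame"))
}

#' Per-property VIKOR runs over the drug index table
#'
#' Runs VIKOR on the (complete) index decision matrix once per physicochemical
#' property, weighting the 11 index criteria by the ratio-normalised absolute
#' correlations of that property with the indices. Falls back to equal
#' weights when a correlation row is unavailable.
#'
#' @param property property id (column of the property table).
#' @param D decision matrix; defaults to the index matrix.
#' @param cor_tab correlation matrix as from [correlation_table()].
#' @param v VIKOR trade-off parameter.
#' @return A `vikor_result`.
#' @export
vikor_property_run <- function(property,
                               D = build_decision_matrix("indices"),
                               cor_tab = correlation_table(load_index_table(),
                                                           load_property_table()),
                               v = 0.5) {
  w <- if (!is.null(cor_tab) && property %in% rownames(cor_tab) &&
           all(colnames(D) %in% colnames(cor_tab)))
    ratio_weights(abs(cor_tab[property, colnames(D)]))
  else equal_weights(ncol(D))
  vikor(D, w, v)
}

#' Rank comparison across MCDM runs
#'
#' Collates the rank columns of one TOPSIS result and any number of VIKOR
#' results into a single table and reports rank agreement.
#'
#' @param topsis_result a `topsis_result`, or `NULL`.
#' @param vikor_results named list of `vikor_result` objects.
#' @return Data frame with column `drug` and one rank column per run, plus
#'   attribute `agreement`: number of drugs with identical rank in every run.
#' @export
rank_report <- function(topsis_result = NULL, vikor_results = list()) {
  runs <- c(if (!is.null(topsis_result)) list(TOPSIS = topsis_result),
            vikor_results)
  if (!length(runs)) stop("no results to compare")
  alts <- runs[[1L]]$alternative
  out <- data.frame(drug = alts)
  for (nm in names(runs)) {
    r <- runs[[nm]]
    stopifnot(setequal(r$alternative, alts))
    out[[nm]] <- r$rank[match(alts, r$alternative)]
  }
  ranks <- as.matrix(out[, -1L, drop = FALSE])
  attr(out, "agreement") <- sum(apply(ranks, 1, function(x) length(unique(x)) == 1L))
  out
}
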