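#' Packaged study tables for the 22 dry-eye-disease drugs
#'
#' The package ships the published study data verbatim as plain-text fixtures:
#' the seven physicochemical properties of the 22 drugs, their eleven
#' topological index values, the seven published regression model
#' specifications, the published predicted-property table, and the
#' Diclofenac molecular graph worked out in full. Values are reproduced
#' exactly as printed, including apparent anomalies; anomalies are surfaced by
#' [validate_index_table()], never edited.
#'
#' @name fixtures
#' @keywords internal
NULL

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "topoqspr", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("fixture file '", name, "' is missing or unreadable")
  path
}

property_units <- c(BP = "degC at 760 mmHg", MR = "cm^3", P = "1e-24 cm^3",
                    MV = "cm^3", E = "kJ/mol", C = "unitless", MW = "g/mol")

read_drug_csv <- function(name, columns) {
  tab <- utils::read.csv(fixture_path(name), check.names = FALSE,
                         na.strings = "NA", stringsAsFactors = FALSE)
  if (!identical(names(tab), c("drug", columns)))
    stop("fixture '", name, "' is corrupted: unexpected columns ",
         paste(names(tab), collapse = ", "))
  if (nrow(tab) != 22L)
    stop("fixture '", name, "' is corrupted: expected 22 drugs, found ", nrow(tab))
  tab
}

#' Load the physicochemical property table
#'
#' Seven properties per drug: boiling point `BP`, molar refractivity `MR`,
#' polarizability `P`, molar volume `MV`, enthalpy of vaporization `E`,
#' complexity `C` and molecular weight `MW`. Five cells are missing in the
#' published table (Lifitegrast BP, Pranoprofen P, Cyclosporine E, Minocycline
#' C and MW) and load as `NA`.
#'
#' @return Data frame of 22 rows with columns `drug`, `BP`, `MR`, `P`, `MV`,
#'   `E`, `C`, `MW`; the units are attached as attribute `units`.
#' @export
load_property_table <- function() {
  tab <- read_drug_csv("properties.csv", names(property_units))
  attr(tab, "units") <- property_units
  tab
}

#' Load the topological index table
#'
#' The published index values for the 22 drugs, as printed. Attribute
#' `validation` carries the report of [validate_index_table()]; rows violating
#' the structural identity `HM = F + 2*M2` are reported there, not corrected.
#'
#' @return Data frame of 22 rows with columns `drug` and the 11
#'   [index_ids()], with a `validation` attribute.
#' @export
load_index_table <- function() {
  tab <- read_drug_csv("indices.csv", index_ids())
  if (anyNA(tab)) stop("fixture 'indices.csv' is corrupted: missing cells")
  attr(tab, "validation") <- validate_index_table(tab)
  tab
}

#' Validate an index table against the hyper-Zagreb identity
#'
#' For any graph, `HM = F + 2*M2` exactly. A published row violating it must
#' contain at least one misprinted cell.
#'
#' @param it data frame with columns `drug`, `M1`, `M2`, `HM`, `F`.
#' @return Data frame with columns `drug`, `HM`, `F`, `M2`,
#'   `identity_residual` (`HM - F - 2*M2`) and logical `flagged`.
#' @examples
#' subset(validate_index_table(load_index_table()), flagged)
#' @export
validate_index_table <- function(it) {
  res <- it$HM - it$F - 2 * it$M2
  data.frame(drug = it$drug, HM = it$HM, F = it$F, M2 = it$M2,
             identity_residual = res, flagged = abs(res) > 1e-9 * pmax(1, it$HM))
}

#' Load the published predicted-property table
#'
#' The predictions printed in the study for each model's response, used by the
#' `predicted` missing-value policy of [build_decision_matrix()]. Its missing
#' cells mirror those of the property table.
#'
#' @return Data frame shaped like [load_property_table()].
#' @export
load_predicted_table <- function() {
  tab <- read_drug_csv("predicted.csv", names(property_units))
  attr(tab, "units") <- property_units
  tab
}

#' Load the seven published regression model specifications
#'
#' Each spec records the response property, the ordered regressor index ids,
#' the printed coefficients and intercept, and the printed fit statistics
#' (`n`, `r`, `R2`, `SE`, `F`, `RMSE`, `p`). Model 1 regresses BP on 8
#' indices; Models 2-7 use the same 10-index set. The Sombor index appears in
#' no model.
#'
#' @return List of 7 `model_spec` objects (lists with fields `id`, `response`,
#'   `regressors`, `intercept`, `coefficients`, `stats`).
#' @export
load_model_specs <- function() {
  js <- jsonlite::read_json(fixture_path("models.json"), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  specs <- lapply(js$models, function(m) {
    m$regressors <- as.character(m$regressors)
    m$coefficients <- stats::setNames(as.numeric(m$coefficients), m$regressors)
    stopifnot(all(m$regressors %in% index_ids()), !"SO" %in% m$regressors)
    structure(m, class = "model_spec")
  })
  stats::setNames(specs, paste0("model", vapply(specs, `[[`, 0, "id")))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d: %s ~ %s\n", x$id, x$response,
              paste(x$regressors, collapse = " + ")))
  cat(sprintf("printed: n=%d r=%.3f R2=%.3f SE=%.3f F=%.3f RMSE=%.3f p=%.3f\n",
              x$stats$n, x$stats$r, x$stats$R2, x$stats$SE, x$stats$F,
              x$stats$RMSE, x$stats$p))
  invisible(x)
}

#' The Diclofenac worked example
#'
#' `diclofenac_partition()` returns the published edge partition of the
#' Diclofenac molecular graph (19 heavy atoms, 20 bonds): 4 edges with
#' endpoint degrees (1,3), 5 with (2,2), 8 with (2,3) and 3 with (3,3).
#' `diclofenac_graph()` loads the packaged edge-list realisation of that
#' graph.
#'
#' @return An [edge_partition()] / a [molecular_graph()].
#' @examples
#' compute_all(diclofenac_partition())
#' @export
diclofenac_partition <- function() {
  as_edge_partition(data.frame(a = c(1L, 2L, 2L, 3L),
                               b = c(3L, 2L, 3L, 3L),
                               count = c(4L, 5L, 8L, 3L)))
}

#' @rdname diclofenac_partition
#' @export
diclofenac_graph <- function() {
  graph_from_edge_list(file = fixture_path("diclofenac_edges.txt"))
}
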