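#' Reproduce the full study analysis from the packaged tables
#'
#' One-command rerun of every stage: fixture validation, recovery of each
#' drug's edge partition from its printed index row and recomputation of the
#' index table, the property-index correlation screen, the seven regression
#' refits with printed-versus-recomputed statistics, the predicted-property
#' table, the TOPSIS ranking, the seven per-property VIKOR rankings and their
#' rank-comparison table, plus a deviations report collecting every anomaly
#' (identity violations, infeasible recoveries, missing-value substitutions,
#' statistic deviations). All outputs are fixed-precision CSV/JSON, so two
#' runs produce byte-identical files.
#'
#' @param out_dir output directory, created if needed.
#' @param topsis_source,topsis_policy configuration of the TOPSIS decision
#'   matrix (defaults: property matrix, `predicted` missing-value policy,
#'   equal weights).
#' @param v VIKOR trade-off parameter.
#' @return Invisibly, a list with every computed object and `files`, the paths
#'   written.
#' @export
reproduce_all <- function(out_dir, topsis_source = "properties",
                          topsis_policy = "predicted", v = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt_csv <- function(df, digits, file) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) {
      out <- ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
      sub("^(-?\\d+)\\.$", "\\1", out)
    })
    lines <- c(paste(names(df), collapse = ","),
               do.call(paste, c(df, sep = ",")))
    writeLines(lines, file.path(out_dir, file))
    file.path(out_dir, file)
  }
  files <- character()
  message("loading fixtures")
  pt <- load_property_table()
  it <- load_index_table()
  validation <- attr(it, "validation")

  message("recovering edge partitions from printed index rows")
  idx_rec <- list(); infeasible <- list()
  for (i in seq_len(nrow(it))) {
    iv <- unlist(it[i, index_ids()])
    res <- tryCatch(recover_partition(iv), topoqspr_infeasible = identity)
    if (inherits(res, "topoqspr_infeasible")) {
      infeasible[[it$drug[i]]] <- conditionMessage(res)
      row <- as.data.frame(t(c(recovered = 0, residual = NA_real_,
                               unique = NA)))
      row <- cbind(row, as.data.frame(t(iv * NA_real_)))
    } else {
      row <- cbind(data.frame(recovered = 1, residual = attr(res, "residual"),
                              unique = as.integer(attr(res, "unique"))),
                   as.data.frame(t(compute_all(res))))
    }
    idx_rec[[i]] <- cbind(data.frame(drug = it$drug[i]), row)
  }
  idx_rec <- do.call(rbind, idx_rec)
  files <- c(files, fmt_csv(idx_rec, 3, "indices_recomputed.csv"))

  message("correlation screening")
  ct <- correlation_table(it, pt)
  ct_df <- cbind(data.frame(property = rownames(ct)), as.data.frame(unclass(ct)))
  files <- c(files, fmt_csv(ct_df, 3, "correlation_table.csv"))

  message("refitting regression models")
  rep_m <- reproduce_models(pt, it)
  files <- c(files, fmt_csv(rep_m$comparison, 3, "model_statistics.csv"))
  preds <- data.frame(drug = it$drug)
  for (nm in names(rep_m$fits)) {
    f <- rep_m$fits[[nm]]
    preds[[f$spec$response]] <- unname(predict(f, it))
  }
  files <- c(files, fmt_csv(preds, 3, "predictions.csv"))

  message("TOPSIS ranking")
  Dt <- build_decision_matrix(topsis_source, topsis_policy, pt = pt, it = it)
  tp <- topsis(Dt)
  files <- c(files, fmt_csv(as.data.frame(tp), 7, "topsis.csv"))

  message("VIKOR per-property rankings")
  Di <- build_decision_matrix("indices", pt = pt, it = it)
  vik <- lapply(rownames(ct), function(p) vikor_property_run(p, Di, ct, v = v))
  names(vik) <- rownames(ct)
  for (p in names(vik))
    files <- c(files, fmt_csv(as.data.frame(vik[[p]]), 6,
                              paste0("vikor_", p, ".csv")))
  cmp <- rank_report(NULL, vik)
  files <- c(files, fmt_csv(cmp, 0, "vikor_rank_comparison.csv"))

  message("writing deviations report")
  report <- list(
    index_identity_violations = validation[validation$flagged, , drop = FALSE],
    recovery_infeasible = infeasible,
    substitutions = attr(Dt, "substitutions"),
    model_statistic_deviations = rep_m$comparison,
    topsis_rank1 = tp$alternative[tp$rank == 1L],
    topsis_rank_last = tp$alternative[tp$rank == nrow(tp)],
    vikor_rank1_all_runs = Reduce(intersect, lapply(vik, function(r)
      r$alternative[r$rank == 1L])),
    vikor_rank_agreement = attr(cmp, "agreement"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  files <- c(files, file.path(out_dir, "report.json"))

  invisible(list(index_table_recomputed = idx_rec, correlations = ct,
                 models = rep_m, predictions = preds, topsis = tp,
                 vikor = vik, comparison = cmp, report = report,
                 files = files))
}
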