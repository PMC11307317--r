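## Tabular readers/writers for the pipeline's plain-text formats.

#' Read heat-flow series from an IMC CSV export
#'
#' Expected columns: `time_h`, `power`, `unit` ("uW" or "W"), `replicate`,
#' `passage`, `condition`. Power is converted to watts.
#'
#' @param path CSV file.
#' @return Named list of [heatflow_series()], one per
#'   (condition, passage, replicate), named
#'   `"<condition>_p<passage>_<replicate>"`.
#' @export
read_heatflow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "power", "unit", "replicate", "passage", "condition")
  if (!all(need %in% names(df)))
    stop_bad_arg("heat-flow CSV needs columns: ", paste(need, collapse = ", "))
  bad_unit <- setdiff(unique(df$unit), c("uW", "W"))
  if (length(bad_unit))
    stop_bad_arg("unknown power unit(s): ", paste(bad_unit, collapse = ", "))
  df$power_W <- ifelse(df$unit == "uW", df$power * 1e-6, df$power)
  parts <- split(df, list(df$condition, df$passage, df$replicate), drop = TRUE)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_h), ]
    heatflow_series(d$time_h, d$power_W, replicate = d$replicate[1],
                    passage = d$passage[1], condition = d$condition[1])
  })
  names(out) <- vapply(out, function(s)
    sprintf("%s_p%d_%s", s$condition, s$passage, s$replicate), "")
  out[order(names(out))]
}

#' Write heat-flow series to the IMC CSV format
#'
#' @param series_list List of [heatflow_series()].
#' @param path Output CSV path.
#' @param unit `"uW"` or `"W"`.
#' @return The path, invisibly.
#' @export
write_heatflow_csv <- function(series_list, path, unit = "uW") {
  unit <- match.arg(unit, c("uW", "W"))
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(time_h = s$time_h,
               power = if (unit == "uW") s$power_W * 1e6 else s$power_W,
               unit = unit, replicate = s$replicate, passage = s$passage,
               condition = s$condition, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a heat curve as CSV (`time_h`, `heat_J`)
#' @param curve A `heat_curve`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_heat_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_h = curve$time_h, heat_J = curve$heat_J),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an abundance TSV (`time_h`, `strain`, `reads`)
#'
#' @param path TSV file.
#' @param copy_numbers Named vector of 16S copy numbers per strain.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path, copy_numbers) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_h", "strain", "reads")
  if (!all(need %in% names(df)))
    stop_bad_arg("abundance TSV needs columns: ", paste(need, collapse = ", "))
  abundance_table(df$time_h, df$strain, df$reads, copy_numbers)
}

#' Write an abundance table as TSV
#' @param ab An [abundance_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance_tsv <- function(ab, path) {
  utils::write.table(ab[, c("time_h", "strain", "reads")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format metabolite CSV
#'
#' Expected columns: `sample`, `replicate`, `metabolite`, `timepoint`,
#' `conc_mM`.
#'
#' @param path CSV file.
#' @return Data.frame in the layout consumed by [concentration_deltas()].
#' @export
read_metabolite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "metabolite", "timepoint", "conc_mM")
  if (!all(need %in% names(df)))
    stop_bad_arg("metabolite CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Write a long-format metabolite CSV
#' @param table Metabolite table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metabolite_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
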