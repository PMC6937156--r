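# Tabular output: TSV with the field's rendering conventions — distances to
# exactly 2 decimals (half-up), kinetic quantities in scientific notation
# with 3 significant digits.

.distance_cols <- c("distance", "displacement", "zn_s_gap", "hbond_glu277",
                    "hbond_tyr255", "rmsd")
.kinetic_cols <- c("K_I", "K_I_se", "K_I_sd", "assoc_const", "kcat_over_KM",
                   "kcat_over_KM_sd", "Vmax", "KM", "km_over_vmax",
                   "inv_vmax", "kcat", "rate_M_s", "substrate_M")

#' Write a result table as TSV
#'
#' Tab-separated with a header row. Columns recognized as distances
#' (`distance`, `displacement`, `zn_s_gap`, ...) are rendered with exactly 2
#' decimals (half-up); kinetic columns (`K_I`, `kcat_over_KM`, `Vmax`, ...)
#' in scientific notation with 3 significant digits; everything else as-is.
#' An empty row list yields a header-only file.
#'
#' @param rows data.frame (homogeneous rows).
#' @param path output path.
#' @param footer optional character vector appended as "#"-prefixed lines.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path, footer = NULL) {
  rows <- as.data.frame(rows)
  fmt <- rows
  for (cn in names(fmt)) {
    if (cn %in% .distance_cols && is.numeric(fmt[[cn]]))
      fmt[[cn]] <- sprintf("%.2f", round_half_up(fmt[[cn]], 2))
    else if (cn %in% .kinetic_cols && is.numeric(fmt[[cn]]))
      fmt[[cn]] <- ifelse(is.na(rows[[cn]]), "NA",
                          sprintf("%.2e", rows[[cn]]))
  }
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(fmt), collapse = "\t"), con)
    if (nrow(fmt) > 0)
      utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, na = "NA")
    if (!is.null(footer)) writeLines(paste0("# ", footer), con)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ", ok)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame (footer lines skipped).
#' @export
read_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
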