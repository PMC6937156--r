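# Join per-ligand geometry and kinetics and quantify the geometry-affinity
# association. With four ligands the correlations are descriptive ordering
# statistics; no p-values are attached.

#' Assemble the per-ligand geometry/kinetics table
#'
#' Joins, per ligand: the inhibition constant and catalytic efficiency with
#' three geometric summaries of its complex — the Zn-S gap (catalytic zinc
#' to sulfamoyl sulfur), the N17 to Glu277 OE2 hydrogen bond, and the
#' shortest carboxylate-oxygen to Tyr255 OH hydrogen bond (O16, or O15 where
#' that oxygen is the partner).
#'
#' @param geometry long-format distance table as from
#'   [subsite_distance_reference()] (columns ligand, ligand_atom,
#'   partner_res, partner_atom, metal, distance).
#' @param kinetics data.frame with columns ligand, K_I, kcat_over_KM.
#' @return data.frame of class `tsa_ligand_table`: code, K_I, assoc_const
#'   (1/K_I), kcat_over_KM, zn_s_gap, hbond_glu277, hbond_tyr255.
#' @export
assemble_ligand_table <- function(geometry = subsite_distance_reference(),
                                  kinetics = inhibition_kinetics_reference()) {
  if (nrow(geometry) == 0 || nrow(kinetics) == 0)
    stop("join error: empty geometry or kinetics input")
  gl <- unique(geometry$ligand); kl <- unique(kinetics$ligand)
  only_g <- setdiff(gl, kl); only_k <- setdiff(kl, gl)
  if (length(only_g) + length(only_k) > 0)
    stop("join error: ligand(s) present in one input only: ",
         paste(c(only_g, only_k), collapse = ", "))
  pick <- function(g, what, sel) {
    v <- g$distance[sel]
    if (length(v) == 0) stop("geometry lacks ", what, " for ",
                             g$ligand[1])
    min(v)
  }
  rows <- lapply(kl, function(lg) {
    g <- geometry[geometry$ligand == lg, ]
    k <- kinetics[kinetics$ligand == lg, ][1, ]
    data.frame(
      code = lg,
      K_I = k$K_I,
      assoc_const = 1 / k$K_I,
      kcat_over_KM = k$kcat_over_KM,
      zn_s_gap = pick(g, "Zn-S18",
                      g$ligand_atom == "S18" & !is.na(g$metal) &
                        g$metal == "ZN"),
      hbond_glu277 = pick(g, "N17-Glu277 OE2",
                          g$ligand_atom == "N17" & is.na(g$metal) &
                            g$partner_res == "GLU" & g$partner_atom == "OE2"),
      hbond_tyr255 = pick(g, "carboxylate O-Tyr255 OH",
                          g$ligand_atom %in% c("O15", "O16") & is.na(g$metal) &
                            g$partner_res == "TYR" & g$partner_atom == "OH"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tsa_ligand_table", "data.frame")
  out
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param xs,ys equal-length numeric vectors, n >= 3.
#' @return rho in [-1, 1]; NA (with a warning) when either rank vector has
#'   zero variance.
#' @export
spearman_rho <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("unequal lengths")
  if (length(xs) < 3) stop("need n >= 3, got ", length(xs))
  rx <- rank(xs, ties.method = "average")
  ry <- rank(ys, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("undefined correlation: zero variance in ranks")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Correlation summary for a ligand table
#'
#' @param records a `tsa_ligand_table` (>= 3 rows for correlations).
#' @return list: spearman_affinity_gap (1/K_I vs Zn-S gap),
#'   spearman_efficiency_affinity (kcat/KM vs 1/K_I), pearson_log (Pearson of
#'   log10(1/K_I) vs Zn-S gap), n; correlations are NA when n < 3.
#' @export
correlation_summary <- function(records) {
  n <- nrow(records)
  if (n < 3)
    return(list(spearman_affinity_gap = NA_real_,
                spearman_efficiency_affinity = NA_real_,
                pearson_log = NA_real_, n = n))
  list(spearman_affinity_gap = spearman_rho(records$assoc_const,
                                            records$zn_s_gap),
       spearman_efficiency_affinity =
         spearman_rho(records$kcat_over_KM, records$assoc_const),
       pearson_log = stats::cor(log10(records$assoc_const),
                                records$zn_s_gap),
       n = n)
}

#' Write the per-ligand report
#'
#' TSV of the ligand table plus a correlation-summary footer; optionally a
#' dual-axis log plot (SVG) of association constant and catalytic efficiency
#' against the Zn-S gap.
#'
#' @param records a `tsa_ligand_table` (>= 1 row).
#' @param path output TSV path.
#' @param plot optional SVG path.
#' @return invisibly, the [correlation_summary()].
#' @export
write_report <- function(records, path, plot = NULL) {
  if (nrow(records) < 1) stop("no records to report")
  cs <- correlation_summary(records)
  footer <- if (cs$n < 3) {
    "correlations: not computable (n < 3)"
  } else {
    c(sprintf("spearman(1/K_I, Zn-S gap) = %.3f", cs$spearman_affinity_gap),
      sprintf("spearman(kcat/KM, 1/K_I) = %.3f",
              cs$spearman_efficiency_affinity),
      sprintf("pearson(log10(1/K_I), Zn-S gap) = %.3f", cs$pearson_log),
      sprintf("n = %d", cs$n))
  }
  write_table(records, path, footer = footer)
  if (!is.null(plot)) {
    ok <- tryCatch({
      grDevices::svg(plot, width = 6, height = 4.5)
      on.exit(grDevices::dev.off(), add = TRUE)
      ord <- order(records$zn_s_gap)
      r <- records[ord, ]
      graphics::par(mar = c(4, 4, 1, 4))
      graphics::plot(r$zn_s_gap, log10(r$assoc_const), type = "b", pch = 18,
                     col = "blue", xlab = "Zn-S gap (A)",
                     ylab = "log10 1/K_I (1/M)")
      graphics::par(new = TRUE)
      graphics::plot(r$zn_s_gap, log10(r$kcat_over_KM), type = "b", pch = 15,
                     col = "red", axes = FALSE, xlab = "", ylab = "")
      graphics::axis(4)
      graphics::mtext("log10 kcat/KM (1/(M s))", side = 4, line = 2.5)
      TRUE
    }, error = function(e) {
      warning("plot skipped: ", conditionMessage(e)); FALSE
    })
  }
  invisible(cs)
}
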