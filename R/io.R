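# Tabular and JSON I/O for measurements, flux tables, parameter sets and
# fit results.

#' Read a phosphorylation measurement table
#'
#' Tab-separated with columns `strain`, `condition`, `ptsN_fraction` and
#' optionally `rel_error`.  Rows are validated (known labels, fractions in
#' `[0, 1]`); offending rows are reported with their line numbers.
#'
#' @param path file path.
#' @return A validated data frame of measurements.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "ptsN_fraction")
  if (!all(need %in% names(tab))) {
    stop("measurement table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad_strain <- which(!(tab$strain %in% PTS_STRAINS))
  if (length(bad_strain)) {
    problems <- c(problems, sprintf(
      "line %d: unknown strain '%s' (allowed: %s)", bad_strain + 1,
      tab$strain[bad_strain], paste(PTS_STRAINS, collapse = ", ")))
  }
  bad_cond <- which(!(tab$condition %in% PTS_CONDITIONS))
  if (length(bad_cond)) {
    problems <- c(problems, sprintf(
      "line %d: unknown condition '%s' (allowed: %s)", bad_cond + 1,
      tab$condition[bad_cond], paste(PTS_CONDITIONS, collapse = ", ")))
  }
  bad_frac <- which(!is.finite(tab$ptsN_fraction) |
                      tab$ptsN_fraction < 0 | tab$ptsN_fraction > 1)
  if (length(bad_frac)) {
    problems <- c(problems, sprintf(
      "line %d: ptsN_fraction outside [0, 1]", bad_frac + 1))
  }
  if (length(problems)) {
    stop("invalid measurement table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tab
}

#' @rdname read_measurements
#' @param measurements a measurement data frame.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a node flux table
#'
#' Tab-separated mirror of the published node-flux summary: columns
#' `condition`, `reaction`, `nominal`, `min`, `max`.
#'
#' @param path file path.
#' @return A flux-table data frame.
#' @export
read_flux_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "reaction", "nominal")
  if (!all(need %in% names(tab))) {
    stop("flux table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname read_flux_table
#' @param flux_table a flux-table data frame.
#' @export
write_flux_table <- function(flux_table, path) {
  utils::write.table(flux_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a parameter set or fit to JSON
#'
#' Parameter sets are written with explicit field names (`k1`..`k5`,
#' `K1`..`K5`, totals, `pp`, `r_fru`); fits with their constants,
#' per-condition ratios and diagnostics summary.
#'
#' @param params a [pts_parameters()] or `"pts_fit"` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_parameters_json <- function(params, path) {
  obj <- if (inherits(params, "pts_parameters")) {
    c(as.list(params$k), as.list(params$K), as.list(params$totals),
      list(pp = params$pp, r_fru = params$r_fru))
  } else if (inherits(params, "pts_fit")) {
    list(Keq = params$Keq, K5 = params$K5, K = as.list(params$K),
         pp = as.list(params$pp), k4 = params$k4, r_fru = params$r_fru,
         mean_rel_residual = params$diagnostics$mean_rel_residual)
  } else {
    stop("cannot serialize object of class ", class(params)[1],
         call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @return `read_parameters_json()` returns a [pts_parameters()] object.
#' @export
read_parameters_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("k1", "K1", "ptsP0") %in% names(obj))) {
    return(pts_parameters(
      k1 = obj$k1, k2 = obj$k2, k3 = obj$k3, k4 = obj$k4, k5 = obj$k5,
      K1 = obj$K1, K2 = obj$K2, K3 = obj$K3, K4 = obj$K4, K5 = obj$K5,
      ptsP0 = obj$ptsP0, ptsO0 = obj$ptsO0, ptsN0 = obj$ptsN0,
      fruB0 = obj$fruB0, pp = obj$pp, r_fru = obj$r_fru))
  }
  obj
}

#' Read or write a strain x condition design table
#'
#' Tab-separated with columns `strain`, `condition`, `pp` (optional),
#' `r_fru`, `fruB_induced`.
#'
#' @param path file path.
#' @return A design data frame.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "r_fru", "fruB_induced")
  if (!all(need %in% names(tab))) {
    stop("design table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$fruB_induced <- as.logical(tab$fruB_induced)
  tab
}

#' @rdname read_design
#' @param design a design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
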