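#' Percent change in modification between unbound and bound states
#'
#' Differential covalent labeling compares the degree of modification of each
#' labeled residue in the free subunit (\code{M_unbound}) and in the complex
#' (\code{M_bound}). The modification change is
#' \deqn{100 (M_{unbound} - M_{bound}) / M_{unbound}}
#' in percent: large positive values indicate strong protection on binding
#' (interface burial), negative values indicate increased labeling. The
#' statistic is invariant to a common rescaling of both measurements, so
#' modification rates and modification extents give identical changes.
#'
#' @param m_unbound Degree of modification in the unbound state; must be
#'   strictly positive (the change is undefined at zero).
#' @param m_bound Degree of modification in the bound state; non-negative,
#'   same units as \code{m_unbound}.
#' @return Modification change in percent (vectorized); always <= 100.
#' @export
#' @examples
#' modification_change(0.5, 0.1)  # 80% protection
#' modification_change(0.2, 0.3)  # -50%: labeling increased on binding
modification_change <- function(m_unbound, m_bound) {
  stopifnot(is.numeric(m_unbound), is.numeric(m_bound))
  if (any(!is.finite(m_unbound)) || any(!is.finite(m_bound)))
    stop("degrees of modification must be finite", call. = FALSE)
  if (any(m_unbound <= 0))
    stop("modification change is undefined for M_unbound <= 0; ",
         "exclude such residues upstream", call. = FALSE)
  if (any(m_bound < 0))
    stop("M_bound cannot be negative", call. = FALSE)
  (m_unbound - m_bound) / m_unbound * 100
}

#' Threshold classification of modification changes
#'
#' @param change Modification change(s) in percent.
#' @param threshold Threshold in percent (> 0); 40 by default convention.
#' @return Logical vector, \code{TRUE} where \code{change >= threshold}
#'   (boundary inclusive).
#' @export
classify_by_change <- function(change, threshold = 40) {
  stopifnot(is.numeric(change), is.numeric(threshold), threshold > 0)
  change >= threshold
}

#' Fit the linear calibration of modification change on interface distance
#'
#' Ordinary least squares of modification change (percent, response) on
#' interface distance (Angstrom, predictor), pooled across complexes. The
#' pooled benchmark fit in the published calibration has slope -2.07,
#' intercept 46.27 and R^2 = 0.36.
#'
#' @param distance Interface distances in Angstrom (>= 2 distinct values).
#' @param change Modification changes in percent, same length.
#' @return A \code{cl_calibration} with slope, intercept, \code{r_squared},
#'   \code{rmse}, \code{nrmse} (RMSE normalized by the mean observed change)
#'   and \code{n_points}.
#' @export
#' @examples
#' d <- c(2, 5, 9, 14, 20)
#' fit_calibration(d, -2 * d + 40)   # recovers the exact line
fit_calibration <- function(distance, change) {
  stopifnot(is.numeric(distance), is.numeric(change))
  ok <- is.finite(distance) & is.finite(change)
  distance <- distance[ok]; change <- change[ok]
  n <- length(distance)
  if (n != length(change))
    stop("distance and change must have the same length", call. = FALSE)
  if (n < 2L)
    stop("insufficient data: need at least 2 points to fit the calibration",
         call. = FALSE)
  if (length(unique(distance)) < 2L)
    stop("degenerate fit: all interface distances are identical",
         call. = FALSE)
  fit <- stats::lm(change ~ distance)
  co <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  ss_tot <- sum((change - mean(change))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  mean_y <- mean(change)
  nrmse <- if (abs(mean_y) > .Machine$double.eps) rmse / mean_y else NA_real_
  calibration_model(slope = unname(co["distance"]),
                    intercept = unname(co["(Intercept)"]),
                    r_squared = min(max(r2, 0), 1), rmse = rmse,
                    nrmse = nrmse, n_points = n)
}

#' Predict a modification change from an interface distance
#'
#' Applies the calibration line \code{slope * distance + intercept}. No
#' clamping is performed: predictions at large distance are negative, which
#' is the behaviour the deviation-based penalty expects.
#'
#' @param distance Interface distance(s) in Angstrom, non-negative.
#' @param calib A \code{cl_calibration}; the published constants by default.
#' @return Predicted modification change(s) in percent.
#' @export
#' @examples
#' predict_modification_change(0)    # 46.27 at the interface
#' predict_modification_change(10)   # 25.57
predict_modification_change <- function(distance,
                                        calib = calibration_model()) {
  stopifnot(inherits(calib, "cl_calibration"), is.numeric(distance))
  if (any(distance < 0, na.rm = TRUE))
    stop("interface distance cannot be negative", call. = FALSE)
  calib$slope * distance + calib$intercept
}

labeling_columns <- c("complex_id", "chain", "residue_number", "residue_name",
                      "measure_kind", "M_unbound", "M_bound")

#' Load a differential-labeling table
#'
#' Reads a tab-separated table of per-residue degrees of modification in the
#' unbound and bound states. Required columns: \code{complex_id},
#' \code{chain} (single letter, or \code{"*"} when the experiment cannot
#' attribute a residue to one chain of a homo-oligomer),
#' \code{residue_number}, \code{residue_name} (3-letter code),
#' \code{measure_kind} (\code{rate} or \code{extent}), \code{M_unbound},
#' \code{M_bound}. Lines starting with \code{#} are ignored. Rows with
#' missing values or \code{M_unbound = 0} are excluded with a message, since
#' their modification change is undefined. \code{measure_kind} must be
#' constant within each complex.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the required columns plus a computed
#'   \code{modification_change} column (percent).
#' @export
load_labeling_table <- function(path) {
  if (!file.exists(path))
    stop("labeling table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(labeling_columns, names(df))
  if (length(missing))
    stop("labeling table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, labeling_columns]
  for (col in c("M_unbound", "M_bound")) {
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'", call. = FALSE)
  }
  if (!all(df$measure_kind %in% c("rate", "extent")))
    stop("measure_kind must be 'rate' or 'extent'", call. = FALSE)
  if (any(df$M_unbound < 0, na.rm = TRUE) || any(df$M_bound < 0, na.rm = TRUE))
    stop("degrees of modification cannot be negative", call. = FALSE)
  kinds <- tapply(df$measure_kind, df$complex_id,
                  function(k) length(unique(k)))
  if (any(kinds > 1L))
    stop("mixed measure_kind within complex(es): ",
         paste(names(kinds)[kinds > 1L], collapse = ", "), call. = FALSE)
  bad <- is.na(df$M_unbound) | is.na(df$M_bound) | df$M_unbound == 0
  if (any(bad)) {
    message(sprintf("load_labeling_table('%s'): excluded %d row(s) with missing measurements or M_unbound = 0",
                    basename(path), sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop("no usable rows in labeling table '", path, "'", call. = FALSE)
  df$residue_number <- as.integer(df$residue_number)
  df$chain <- as.character(df$chain)
  df$modification_change <- modification_change(df$M_unbound, df$M_bound)
  rownames(df) <- NULL
  df
}

#' Write a differential-labeling table
#'
#' Inverse of [load_labeling_table()]; writes the required columns as TSV.
#'
#' @param labeled Data frame with the labeling-table columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_labeling_table <- function(labeled, path) {
  missing <- setdiff(labeling_columns, names(labeled))
  if (length(missing))
    stop("labeling data missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  utils::write.table(labeled[, labeling_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map one labeled residue onto a structure's interface distance
#'
#' Resolves a labeling-table row against a structure. A concrete chain must
#' match exactly one residue (ambiguous insertion codes are an error). The
#' wildcard chain \code{"*"} maps the residue onto every chain that carries a
#' residue of that number and name, and returns the minimum interface
#' distance over the copies: for a homo-oligomer the experiment cannot
#' attribute the signal to a chain, and protection would be observed if any
#' copy buries.
#'
#' @param structure A \code{cl_structure}.
#' @param spec A \code{cl_partners}.
#' @param chain Chain id or \code{"*"}.
#' @param resno Residue number.
#' @param resname Optional 3-letter residue name; when given, candidate
#'   residues must match it.
#' @return Interface distance in Angstrom, or \code{NA_real_} when the
#'   residue cannot be mapped (caller counts skips).
#' @export
labeled_residue_distance <- function(structure, spec, chain, resno,
                                     resname = NULL) {
  res <- structure_residues(structure)
  in_spec <- res$chain %in% c(spec$group_a, spec$group_b)
  cand <- res[in_spec & res$resno == resno, , drop = FALSE]
  if (!is.null(resname) && nzchar(resname))
    cand <- cand[cand$resid == toupper(resname), , drop = FALSE]
  if (chain != "*") {
    cand <- cand[cand$chain == chain, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_real_)
    if (nrow(cand) > 1L)
      stop(sprintf("residue %s%d is ambiguous (multiple insertion codes) in '%s'",
                   chain, resno, structure$model_id), call. = FALSE)
  } else if (nrow(cand) == 0L) {
    return(NA_real_)
  }
  min(vapply(seq_len(nrow(cand)), function(i) {
    interface_distance(structure, spec, cand$chain[i], cand$resno[i],
                       cand$insert[i])
  }, numeric(1L)))
}
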