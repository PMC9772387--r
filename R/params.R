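#' Scoring parameters for covalent-labeling rescoring
#'
#' Bundles the tunable constants of the labeling-guided score: the steepness
#' \code{A} and midpoint \code{B} of the sigmoidal per-residue penalty, the
#' weight applied to the normalized labeling score term before it is added to
#' the interface energy, the heavy-atom distance cutoff that defines an
#' interface residue, and the modification-change threshold used for
#' interface classification diagnostics.
#'
#' Defaults are the published calibration: \code{A = 1.88} per percent,
#' \code{B = 38.0} percent, \code{weight = 65}, \code{interface_cutoff = 10}
#' Angstrom and \code{change_threshold = 40} percent.
#'
#' @param A Sigmoid steepness, per percent deviation. Must be > 0.
#' @param B Sigmoid midpoint in percent deviation; the penalty is exactly 0.5
#'   when the deviation equals \code{B}. Must be > 0.
#' @param weight Dimensionless multiplier on the normalized labeling score
#'   term. \code{weight = 0} reduces ranking to the interface energy alone.
#' @param interface_cutoff Heavy-atom distance (Angstrom) at or below which a
#'   residue counts as part of the binding interface.
#' @param change_threshold Modification change (percent) at or above which a
#'   residue is classified as strongly protected for diagnostic counts.
#' @param deviation_mode Either \code{"abs"} (default; deviation is the
#'   absolute difference between experimental and predicted modification
#'   change) or \code{"signed"} (experimental minus predicted, for
#'   sensitivity analysis).
#'
#' @return An object of class \code{cl_params}.
#' @export
#' @examples
#' p <- scoring_params()
#' penalty(p$B, p)  # 0.5 at the midpoint
scoring_params <- function(A = 1.88, B = 38.0, weight = 65,
                           interface_cutoff = 10, change_threshold = 40,
                           deviation_mode = c("abs", "signed")) {
  deviation_mode <- match.arg(deviation_mode)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0)
  stopifnot(is.numeric(B), length(B) == 1L, is.finite(B), B > 0)
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight),
            weight >= 0)
  stopifnot(is.numeric(interface_cutoff), interface_cutoff > 0)
  stopifnot(is.numeric(change_threshold), change_threshold > 0)
  structure(list(A = A, B = B, weight = weight,
                 interface_cutoff = interface_cutoff,
                 change_threshold = change_threshold,
                 deviation_mode = deviation_mode),
            class = "cl_params")
}

#' @export
print.cl_params <- function(x, ...) {
  cat("Covalent-labeling scoring parameters\n")
  cat(sprintf("  sigmoid: A = %g /%%, B = %g %%\n", x$A, x$B))
  cat(sprintf("  weight on normalized CL term: %g\n", x$weight))
  cat(sprintf("  interface cutoff: %g A; change threshold: %g %%\n",
              x$interface_cutoff, x$change_threshold))
  cat(sprintf("  deviation mode: %s\n", x$deviation_mode))
  invisible(x)
}

#' Linear calibration between modification change and interface distance
#'
#' Holds the slope and intercept of the line relating modification change
#' (percent, y) to interface distance (Angstrom, x), plus fit diagnostics
#' when the model was fitted from data. Unfitted defaults are the published
#' pooled-benchmark constants: slope -2.07 percent per Angstrom, intercept
#' 46.27 percent.
#'
#' @param slope Percent modification change per Angstrom of interface
#'   distance (negative: protection decays with distance).
#' @param intercept Predicted modification change (percent) at zero distance.
#' @param r_squared Coefficient of determination of the fit, or \code{NA}.
#' @param rmse Root-mean-square error of the fit in percent, or \code{NA}.
#' @param nrmse RMSE divided by the mean observed modification change, or
#'   \code{NA}.
#' @param n_points Number of (distance, change) points used in the fit; 0 for
#'   the default, unfitted model.
#'
#' @return An object of class \code{cl_calibration}.
#' @seealso [fit_calibration()], [predict_modification_change()]
#' @export
calibration_model <- function(slope = -2.07, intercept = 46.27,
                              r_squared = NA_real_, rmse = NA_real_,
                              nrmse = NA_real_, n_points = 0L) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = as.numeric(r_squared), rmse = as.numeric(rmse),
                 nrmse = as.numeric(nrmse), n_points = as.integer(n_points)),
            class = "cl_calibration")
}

#' @export
print.cl_calibration <- function(x, ...) {
  cat("Distance -> modification-change calibration\n")
  cat(sprintf("  change %% = %.4g x distance(A) + %.4g\n", x$slope,
              x$intercept))
  if (x$n_points > 0L) {
    cat(sprintf("  fitted on %d points: R^2 = %.3f, RMSE = %.3f %%, NRMSE = %.3f\n",
                x$n_points, x$r_squared, x$rmse, x$nrmse))
  } else {
    cat("  (default constants, not fitted)\n")
  }
  invisible(x)
}

#' Write a calibration model to a flat key=value file
#'
#' @param calib A \code{cl_calibration} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "cl_calibration"))
  keys <- c("slope", "intercept", "r_squared", "rmse", "nrmse", "n_points")
  lines <- vapply(keys, function(k) {
    v <- calib[[k]]
    sprintf("%s=%s", k, format(v, digits = 17))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration model from a flat key=value file
#'
#' @param path File written by [write_calibration()] (lines starting with
#'   \code{#} are ignored).
#' @return A \code{cl_calibration} object.
#' @export
read_calibration <- function(path) {
  kv <- read_key_value(path)
  need <- c("slope", "intercept")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop("calibration file missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- function(k, default = NA_real_) {
    if (k %in% names(kv)) suppressWarnings(as.numeric(kv[[k]])) else default
  }
  calibration_model(slope = num("slope"), intercept = num("intercept"),
                    r_squared = num("r_squared"), rmse = num("rmse"),
                    nrmse = num("nrmse"),
                    n_points = as.integer(num("n_points", 0)))
}

#' Read a configuration file of scoring parameters
#'
#' Accepts either YAML or flat \code{key=value} text. Recognized keys:
#' \code{A}, \code{B}, \code{weight}, \code{interface_cutoff},
#' \code{change_threshold}, \code{deviation_mode}, \code{slope},
#' \code{intercept}. Unrecognized keys raise an error so typos do not pass
#' silently.
#'
#' @param path Config file path.
#' @return A list with elements \code{params} (a \code{cl_params}) and
#'   \code{calibration} (a \code{cl_calibration}, defaults where the file is
#'   silent).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  vals <- if (any(grepl(":", txt, fixed = TRUE)) &&
              !any(grepl("=", txt, fixed = TRUE))) {
    yaml::read_yaml(path)
  } else {
    as.list(read_key_value(path))
  }
  known <- c("A", "B", "weight", "interface_cutoff", "change_threshold",
             "deviation_mode", "slope", "intercept")
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  defaults <- scoring_params()
  get_num <- function(k, d) if (!is.null(vals[[k]])) as.numeric(vals[[k]]) else d
  params <- scoring_params(
    A = get_num("A", defaults$A),
    B = get_num("B", defaults$B),
    weight = get_num("weight", defaults$weight),
    interface_cutoff = get_num("interface_cutoff", defaults$interface_cutoff),
    change_threshold = get_num("change_threshold", defaults$change_threshold),
    deviation_mode = if (!is.null(vals$deviation_mode))
      as.character(vals$deviation_mode) else "abs")
  dcal <- calibration_model()
  calib <- calibration_model(slope = get_num("slope", dcal$slope),
                             intercept = get_num("intercept", dcal$intercept))
  list(params = params, calibration = calib)
}

# Parse flat key=value text, skipping blank and '#' comment lines.
read_key_value <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (!all(grepl("=", txt, fixed = TRUE)))
    stop("malformed key=value file: ", path, call. = FALSE)
  keys <- trimws(sub("=.*$", "", txt))
  vals <- trimws(sub("^[^=]*=", "", txt))
  stats::setNames(vals, keys)
}
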