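#' Sigmoidal per-residue penalty
#'
#' Each labeled residue of a docked model contributes a penalty
#' \deqn{P = 1 - \frac{1}{1 + e^{A (d - B)}}}
#' where \eqn{d} is the deviation (percent) between the experimentally
#' observed modification change and the change predicted from the model's
#' interface distance. The penalty is a logistic sigmoid: near 0 for
#' deviations well below the midpoint \eqn{B}, exactly 0.5 at \eqn{d = B},
#' and approaching 1 for large disagreement.
#'
#' @param d Deviation(s) in percent; non-negative in the default absolute
#'   deviation mode.
#' @param params A \code{cl_params}; defaults A = 1.88, B = 38.0.
#' @return Penalty value(s) in (0, 1).
#' @export
#' @examples
#' penalty(38)   # 0.5 at the midpoint
#' penalty(0)    # effectively 0
penalty <- function(d, params = scoring_params()) {
  stopifnot(inherits(params, "cl_params"), is.numeric(d))
  stats::plogis(params$A * (d - params$B))
}

#' Deviation between experimental and predicted modification change
#'
#' By default the absolute difference: disagreement is penalized regardless
#' of its sign, so a model that buries a residue the data say is exposed is
#' treated like one that exposes a residue the data say is buried. The
#' \code{"signed"} mode (experimental minus predicted) is available for
#' sensitivity analysis; it assigns near-zero penalty to any over-prediction.
#'
#' @param experimental Observed modification change(s), percent.
#' @param predicted Predicted modification change(s), percent.
#' @param mode \code{"abs"} (default) or \code{"signed"}.
#' @return Deviation(s) in percent.
#' @export
residue_deviation <- function(experimental, predicted,
                              mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(experimental), is.numeric(predicted))
  if (any(!is.finite(experimental)) || any(!is.finite(predicted)))
    stop("modification changes must be finite", call. = FALSE)
  d <- experimental - predicted
  if (mode == "abs") abs(d) else d
}

#' Raw covalent-labeling score term of one docked model
#'
#' For every labeled residue that can be mapped onto the model, the model's
#' interface distance is converted to a predicted modification change via the
#' calibration line, the deviation from the experimental change is fed
#' through the sigmoidal [penalty()], and the penalties are summed. Labeled
#' residues absent from the model are skipped and counted. All residues with
#' a defined modification change enter the sum; the classification threshold
#' is a diagnostic device, not a scoring filter.
#'
#' @param model A \code{cl_structure}.
#' @param spec A \code{cl_partners}.
#' @param labeled Labeling data frame as returned by
#'   [load_labeling_table()].
#' @param calib A \code{cl_calibration}.
#' @param params A \code{cl_params}.
#' @return List with \code{raw} (non-negative penalty sum),
#'   \code{n_scored} and \code{n_skipped}.
#' @export
cl_score_term_raw <- function(model, spec, labeled,
                              calib = calibration_model(),
                              params = scoring_params()) {
  stopifnot(inherits(model, "cl_structure"), inherits(spec, "cl_partners"),
            is.data.frame(labeled))
  if (!"modification_change" %in% names(labeled))
    labeled$modification_change <- modification_change(labeled$M_unbound,
                                                       labeled$M_bound)
  dists <- vapply(seq_len(nrow(labeled)), function(i) {
    labeled_residue_distance(model, spec, labeled$chain[i],
                             labeled$residue_number[i],
                             labeled$residue_name[i])
  }, numeric(1L))
  mapped <- !is.na(dists)
  if (!any(mapped))
    stop("no labeled residue could be mapped onto model '", model$model_id,
         "'; it cannot be scored against the labeling data", call. = FALSE)
  pred <- predict_modification_change(dists[mapped], calib)
  dev <- residue_deviation(labeled$modification_change[mapped], pred,
                           mode = params$deviation_mode)
  list(raw = sum(penalty(dev, params)),
       n_scored = sum(mapped), n_skipped = sum(!mapped))
}

#' Max-normalize raw score terms over a model set
#'
#' Divides every raw penalty sum by the maximum over the set, so the worst
#' model scores 1 and a model in perfect agreement with the data scores near
#' 0. A degenerate set in which every raw score is 0 (all models agree
#' equally with the data) normalizes to all zeros.
#'
#' @param raw_scores Non-negative numeric vector, non-empty.
#' @return Numeric vector in [0, 1], same length.
#' @export
normalize_over_set <- function(raw_scores) {
  stopifnot(is.numeric(raw_scores), length(raw_scores) >= 1L)
  if (any(!is.finite(raw_scores)))
    stop("raw scores must be finite", call. = FALSE)
  if (any(raw_scores < 0))
    stop("raw covalent-labeling scores cannot be negative", call. = FALSE)
  m <- max(raw_scores)
  if (m == 0) rep(0, length(raw_scores)) else raw_scores / m
}

#' Combined covalent-labeling score
#'
#' The combined score adds the weighted, normalized labeling score term to
#' the externally computed interface energy:
#' \code{score = isc + weight * cl_norm}. Lower is better; with weight 0 the
#' ranking reduces to the interface energy alone.
#'
#' @param isc Interface energy (e.g. a Rosetta interface score), any units;
#'   lower is more favorable.
#' @param cl_norm Normalized labeling score term(s) in [0, 1].
#' @param params A \code{cl_params} (default weight 65).
#' @return Combined score(s), same units as \code{isc}.
#' @export
combined_score <- function(isc, cl_norm, params = scoring_params()) {
  stopifnot(inherits(params, "cl_params"), is.numeric(isc),
            is.numeric(cl_norm))
  if (any(cl_norm < 0 | cl_norm > 1, na.rm = TRUE))
    stop("cl_norm must lie in [0, 1]", call. = FALSE)
  isc + params$weight * cl_norm
}

#' Rescore an ensemble of docked models with labeling data
#'
#' Computes the raw labeling score term for every model, max-normalizes
#' across the ensemble, combines with each model's interface energy, and
#' ranks (rank 1 = lowest combined score). Ties are broken by lower interface
#' energy, then lexicographic model id, so the output is deterministic.
#'
#' @param models Named list of \code{cl_structure} objects (names are model
#'   ids), or an unnamed list (ids taken from each structure's
#'   \code{model_id}).
#' @param isc Named numeric vector of interface energies, or a data frame
#'   with columns \code{model_id} and \code{isc}. Every model must have one.
#' @param spec A \code{cl_partners} valid for every model.
#' @param labeled Labeling data frame ([load_labeling_table()]).
#' @param calib A \code{cl_calibration}.
#' @param params A \code{cl_params}.
#' @return Data frame sorted by rank with columns \code{model_id},
#'   \code{isc}, \code{cl_raw}, \code{cl_norm}, \code{cl_score}, \code{rank},
#'   \code{n_residues_scored}, \code{n_residues_skipped}.
#' @export
rescore_ensemble <- function(models, isc, spec, labeled,
                             calib = calibration_model(),
                             params = scoring_params()) {
  stopifnot(is.list(models), length(models) >= 1L)
  ids <- names(models)
  if (is.null(ids))
    ids <- vapply(models, function(m) m$model_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate model ids in ensemble", call. = FALSE)
  if (is.data.frame(isc)) {
    stopifnot(all(c("model_id", "isc") %in% names(isc)))
    isc <- stats::setNames(as.numeric(isc$isc), isc$model_id)
  }
  missing_isc <- setdiff(ids, names(isc))
  if (length(missing_isc))
    stop("no interface score for model(s): ",
         paste(missing_isc, collapse = ", "), call. = FALSE)
  layouts <- vapply(models, function(m)
    paste(sort(unique(m$atoms$chain)), collapse = ""), character(1L))
  if (length(unique(layouts)) > 1L)
    stop("models in the ensemble have inconsistent chain layouts: ",
         paste(unique(layouts), collapse = " vs "), call. = FALSE)

  terms <- lapply(models, cl_score_term_raw, spec = spec, labeled = labeled,
                  calib = calib, params = params)
  raw <- vapply(terms, `[[`, numeric(1L), "raw")
  n_scored <- vapply(terms, `[[`, integer(1L), "n_scored")
  n_skipped <- vapply(terms, `[[`, integer(1L), "n_skipped")
  if (length(unique(n_scored)) > 1L)
    warning("number of scored labeled residues differs across the ensemble (",
            paste(range(n_scored), collapse = "-"),
            "); raw score terms are not re-weighted", call. = FALSE)
  cl_norm <- normalize_over_set(raw)
  score <- combined_score(isc[ids], cl_norm, params)
  out <- data.frame(model_id = ids, isc = unname(isc[ids]),
                    cl_raw = unname(raw), cl_norm = unname(cl_norm),
                    cl_score = unname(score),
                    n_residues_scored = unname(n_scored),
                    n_residues_skipped = unname(n_skipped),
                    stringsAsFactors = FALSE)
  ord <- order(out$cl_score, out$isc, out$model_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("model_id", "isc", "cl_raw", "cl_norm", "cl_score", "rank",
          "n_residues_scored", "n_residues_skipped")]
}

#' Read a per-model interface-score table
#'
#' Tab-separated file with columns \code{model_id} and \code{isc}; lines
#' starting with \code{#} are ignored. Model ids must match the PDB file
#' stems of the ensemble.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns \code{model_id}, \code{isc}.
#' @export
read_isc_table <- function(path) {
  if (!file.exists(path)) stop("isc table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("model_id", "isc") %in% names(df)))
    stop("isc table must have columns model_id and isc", call. = FALSE)
  if (!is.numeric(df$isc))
    stop("non-numeric interface scores", call. = FALSE)
  df$model_id <- as.character(df$model_id)
  df[, c("model_id", "isc")]
}

#' Write a ranked score table
#'
#' Writes the output of [rescore_ensemble()] as TSV, preceded by a
#' \code{#}-comment header recording the package version and the effective
#' parameters so a run can be reproduced from its output alone.
#'
#' @param scores Data frame from [rescore_ensemble()].
#' @param path Output path.
#' @param params The \code{cl_params} used.
#' @param calib The \code{cl_calibration} used.
#' @param seed Optional integer seed to record.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path, params = scoring_params(),
                              calib = calibration_model(), seed = NULL) {
  hdr <- c(
    sprintf("# clrescore %s",
            as.character(utils::packageVersion("clrescore"))),
    sprintf("# A=%g B=%g weight=%g interface_cutoff=%g change_threshold=%g deviation_mode=%s",
            params$A, params$B, params$weight, params$interface_cutoff,
            params$change_threshold, params$deviation_mode),
    sprintf("# slope=%g intercept=%g", calib$slope, calib$intercept))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed=%d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranked score table written by [write_score_table()]
#'
#' @param path Path to the TSV file.
#' @return Data frame of per-model scores.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}
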