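#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the RMSD between
#' two paired point sets, via the SVD of the covariance matrix with the
#' determinant correction that excludes reflections.
#'
#' @param coords_ref Reference coordinates, n x 3 matrix (Angstrom).
#' @param coords_mobile Mobile coordinates, n x 3 matrix, paired row-by-row
#'   with the reference. At least 3 non-collinear pairs.
#' @return List with \code{rotation} (3 x 3, det = +1), \code{translation}
#'   (length-3), and \code{rmsd} (Angstrom). The aligned mobile set is
#'   \code{coords_mobile \%*\% rotation + translation} (row-wise).
#' @export
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(x, x)$rmsd  # 0
kabsch_superpose <- function(coords_ref, coords_mobile) {
  coords_ref <- as.matrix(coords_ref)
  coords_mobile <- as.matrix(coords_mobile)
  if (!all(dim(coords_ref) == dim(coords_mobile)) ||
      ncol(coords_ref) != 3L)
    stop("coordinate sets must be paired n x 3 matrices", call. = FALSE)
  n <- nrow(coords_ref)
  if (n < 3L)
    stop("superposition is underdetermined with fewer than 3 point pairs",
         call. = FALSE)
  c_ref <- colMeans(coords_ref)
  c_mob <- colMeans(coords_mobile)
  q <- sweep(coords_ref, 2L, c_ref)
  p <- sweep(coords_mobile, 2L, c_mob)
  h <- crossprod(p, q)               # 3 x 3 covariance
  sv <- svd(h)
  s <- sign(det(sv$u) * det(sv$v))
  if (s == 0) s <- 1
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  aligned <- p %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - q)^2)))
  list(rotation = rot,
       translation = as.numeric(c_ref - c_mob %*% rot),
       rmsd = rmsd)
}

# Extract the alpha-carbon table of a structure (one CA per residue).
calpha_table <- function(structure) {
  at <- structure$atoms
  ca <- at[at$elety == "CA" & at$element == "C", , drop = FALSE]
  ca[!duplicated(residue_keys(ca)), , drop = FALSE]
}

#' Global alpha-carbon RMSD between a model and a reference complex
#'
#' Pairs alpha carbons by (chain, residue number, insertion code), performs a
#' single joint superposition over all matched residues of all chains (no
#' per-chain fitting, no outlier rejection), and returns the Kabsch RMSD.
#' Residues present in only one structure are dropped with a message.
#'
#' @param model A \code{cl_structure}.
#' @param reference A \code{cl_structure} sharing residue numbering with the
#'   model.
#' @param fit If \code{TRUE} (default) superpose before measuring; if
#'   \code{FALSE}, measure in the shared coordinate frame, as appropriate for
#'   decoys generated in the reference frame.
#' @return RMSD in Angstrom.
#' @export
complex_rmsd <- function(model, reference, fit = TRUE) {
  stopifnot(inherits(model, "cl_structure"),
            inherits(reference, "cl_structure"))
  ca_m <- calpha_table(model)
  ca_r <- calpha_table(reference)
  km <- residue_keys(ca_m)
  kr <- residue_keys(ca_r)
  common <- intersect(km, kr)
  dropped <- (nrow(ca_m) - length(common)) + (nrow(ca_r) - length(common))
  if (dropped > 0L)
    message(sprintf("complex_rmsd: %d unmatched alpha carbon(s) dropped", dropped))
  if (length(common) < 3L)
    stop("fewer than 3 matched alpha-carbon pairs between '",
         model$model_id, "' and '", reference$model_id, "'", call. = FALSE)
  xm <- as.matrix(ca_m[match(common, km), c("x", "y", "z")])
  xr <- as.matrix(ca_r[match(common, kr), c("x", "y", "z")])
  if (fit) {
    kabsch_superpose(xr, xm)$rmsd
  } else {
    sqrt(mean(rowSums((xm - xr)^2)))
  }
}

#' Interface agreement between a structure and labeling data
#'
#' Classifies every mappable labeled residue of a structure by interface
#' membership (shortest heavy-atom distance to the partner at or below the
#' cutoff) and by modification-change threshold, and summarizes the
#' agreement: counts of strongly protected residues inside and outside the
#' interface, and the mean modification change in each class.
#'
#' @param structure A \code{cl_structure} (typically the native complex).
#' @param spec A \code{cl_partners}.
#' @param labeled Labeling data frame ([load_labeling_table()]).
#' @param params A \code{cl_params} supplying the cutoff and threshold.
#' @return List with \code{n_total} (mapped labeled residues),
#'   \code{n_interface} / \code{n_outside} (unthresholded partition),
#'   \code{n_interface_above_threshold}, \code{n_outside_above_threshold},
#'   \code{mean_change_interface}, \code{mean_change_outside}, and
#'   \code{details}, the per-residue classification table.
#' @export
interface_agreement_counts <- function(structure, spec, labeled,
                                       params = scoring_params()) {
  stopifnot(inherits(structure, "cl_structure"),
            inherits(spec, "cl_partners"), is.data.frame(labeled))
  if (!"modification_change" %in% names(labeled))
    labeled$modification_change <- modification_change(labeled$M_unbound,
                                                       labeled$M_bound)
  dists <- vapply(seq_len(nrow(labeled)), function(i) {
    labeled_residue_distance(structure, spec, labeled$chain[i],
                             labeled$residue_number[i],
                             labeled$residue_name[i])
  }, numeric(1L))
  mapped <- !is.na(dists)
  if (any(!mapped))
    message(sprintf("interface_agreement_counts: %d labeled residue(s) not mappable onto '%s'",
                    sum(!mapped), structure$model_id))
  d <- dists[mapped]
  ch <- labeled$modification_change[mapped]
  at_if <- is_interface_residue(d, params$interface_cutoff)
  above <- classify_by_change(ch, params$change_threshold)
  details <- data.frame(labeled[mapped, c("complex_id", "chain",
                                          "residue_number", "residue_name")],
                        interface_distance = d, modification_change = ch,
                        at_interface = at_if, above_threshold = above,
                        stringsAsFactors = FALSE)
  list(n_total = sum(mapped),
       n_interface = sum(at_if),
       n_outside = sum(!at_if),
       n_interface_above_threshold = sum(at_if & above),
       n_outside_above_threshold = sum(!at_if & above),
       mean_change_interface = if (any(at_if)) mean(ch[at_if]) else NA_real_,
       mean_change_outside = if (any(!at_if)) mean(ch[!at_if]) else NA_real_,
       details = details)
}

#' Summarize top-scoring model quality across a benchmark
#'
#' Given the RMSD of the top-scoring model for each complex under two scoring
#' conditions (interface energy alone, and combined with the labeling term),
#' reports the mean RMSD per condition and the number of complexes whose
#' top model falls at or below a success threshold.
#'
#' @param evaluations Data frame with columns \code{complex_id},
#'   \code{rmsd_without_cl} and \code{rmsd_with_cl} (Angstrom).
#' @param success_rmsd Success threshold in Angstrom (default 3.6).
#' @return List with \code{n_complexes}, \code{mean_rmsd_without_cl},
#'   \code{mean_rmsd_with_cl}, \code{n_success_without_cl},
#'   \code{n_success_with_cl} and \code{success_rmsd}.
#' @export
benchmark_summary <- function(evaluations, success_rmsd = 3.6) {
  stopifnot(is.data.frame(evaluations), nrow(evaluations) >= 1L,
            all(c("complex_id", "rmsd_without_cl", "rmsd_with_cl") %in%
                  names(evaluations)))
  list(n_complexes = nrow(evaluations),
       mean_rmsd_without_cl = mean(evaluations$rmsd_without_cl),
       mean_rmsd_with_cl = mean(evaluations$rmsd_with_cl),
       n_success_without_cl = sum(evaluations$rmsd_without_cl <= success_rmsd),
       n_success_with_cl = sum(evaluations$rmsd_with_cl <= success_rmsd),
       success_rmsd = success_rmsd)
}
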