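# Synthetic desk-scale benchmark generators. Everything here is seeded and
# bit-reproducible: the scenario seed fully determines all outputs, and the
# caller's RNG state is left untouched.

# evaluate `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# deterministic sub-stream seeds derived from a scenario seed (kept < 2^31)
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Generate a toy two-chain complex with a defined interface
#'
#' Builds a pseudo-protein dimer (chains A and B) of CA+CB residues. A
#' contiguous block of residues in each chain (about one third, at least 3)
#' forms the binding interface, with heavy-atom partner distances between
#' roughly 3.5 and 9 Angstrom; all remaining residues sit beyond 15 Angstrom
#' from the partner. Coordinates carry small seeded jitter so different seeds
#' give different structures, while the same seed is bit-reproducible.
#'
#' @param n_residues_per_chain Residues per chain (>= 5).
#' @param seed Integer seed.
#' @return A \code{cl_structure} with \code{2 * n_residues_per_chain}
#'   residues.
#' @export
#' @examples
#' s <- make_toy_complex(10, seed = 1)
#' table(s$atoms$chain)
make_toy_complex <- function(n_residues_per_chain, seed = 1) {
  n <- as.integer(n_residues_per_chain)
  stopifnot(n >= 5L)
  k <- max(3L, as.integer(round(n / 3)))
  aa <- c("ALA", "LEU", "LYS", "SER", "THR", "VAL", "PHE", "ARG", "GLY",
          "ASP")
  with_seed(derive_seed(seed, 1L), {
    build_chain <- function(chain, z_interface, z_tail) {
      x <- 4 * (seq_len(n) - 1L)
      z <- c(z_interface, rep(z_tail, n - k))
      ca <- cbind(x, 0, z) + matrix(stats::runif(3L * n, -0.4, 0.4),
                                    ncol = 3L)
      cb <- sweep(ca, 2L, c(0, 1.5, 0), "+") +
        matrix(stats::runif(3L * n, -0.2, 0.2), ncol = 3L)
      data.frame(chain = chain, resno = rep(seq_len(n), each = 2L),
                 insert = "",
                 resid = rep(aa[(seq_len(n) - 1L) %% length(aa) + 1L],
                             each = 2L),
                 elety = rep(c("CA", "CB"), n),
                 element = "C",
                 x = as.vector(rbind(ca[, 1L], cb[, 1L])),
                 y = as.vector(rbind(ca[, 2L], cb[, 2L])),
                 z = as.vector(rbind(ca[, 3L], cb[, 3L])),
                 stringsAsFactors = FALSE)
    }
    # interface block of chain B slopes gently away so interface distances
    # span a range instead of a single value
    z_b <- 4.5 + if (k > 1L) 3.5 * (seq_len(k) - 1L) / (k - 1L) else 0
    atoms <- rbind(build_chain("A", rep(0, k), -25),
                   build_chain("B", z_b, 31))
    new_structure(sprintf("toy_n%d_s%d", n, as.integer(seed)), atoms)
  })
}

#' Write a structure as a PDB file
#'
#' @param structure A \code{cl_structure}.
#' @param path Output PDB path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "cl_structure"))
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, NA),
                   elety = at$elety, elesy = at$element,
                   eleno = seq_len(nrow(at)), o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  invisible(path)
}

# Rodrigues rotation matrix: angle in degrees about unit axis u
rotation_about_axis <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0),
               nrow = 3L)
  diag(3L) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# rigid-body move of the chains in `chains`: rotate about their centroid,
# then translate
transform_partner <- function(structure, chains, rotation, translation) {
  at <- structure$atoms
  sel <- at$chain %in% chains
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  moved <- sweep(xyz, 2L, ctr) %*% rotation
  moved <- sweep(moved, 2L, ctr + translation, "+")
  at[sel, c("x", "y", "z")] <- moved
  new_structure(structure$model_id, at)
}

#' Default rigid-body perturbation schedule for a decoy ensemble
#'
#' A small number of near-native perturbations followed by perturbations of
#' strictly increasing magnitude, emulating a docking ensemble that spans
#' near-native to clearly wrong poses.
#'
#' @param n_decoys Total perturbed decoys (>= 2, native not counted).
#' @param n_near Near-native decoys (small rotation/translation).
#' @param max_translation Largest translation magnitude, Angstrom.
#' @param max_rotation Largest rotation magnitude, degrees.
#' @return Data frame with columns \code{rotation_deg},
#'   \code{translation_ang}, one row per decoy.
#' @export
make_perturbation_schedule <- function(n_decoys = 40, n_near = 2,
                                       max_translation = 30,
                                       max_rotation = 120) {
  stopifnot(n_decoys >= 2, n_near >= 0, n_near < n_decoys)
  n_far <- n_decoys - n_near
  near <- if (n_near > 0)
    data.frame(rotation_deg = 2 * seq_len(n_near),
               translation_ang = 0.4 * seq_len(n_near))
  else NULL
  far <- data.frame(
    rotation_deg = seq(15, max_rotation, length.out = n_far),
    translation_ang = seq(5, max_translation, length.out = n_far))
  rbind(near, far)
}

#' Generate a rigid-body decoy ensemble from a native complex
#'
#' Applies seeded rigid-body perturbations (rotation about the partner
#' centroid around a random axis, then translation along a random direction)
#' to the second docking partner, keeping the first fixed. The unperturbed
#' native is included as decoy 0. Each decoy's alpha-carbon RMSD to the
#' native (after optimal superposition) is computed exactly.
#'
#' @param native A \code{cl_structure} (the reference complex).
#' @param spec A \code{cl_partners}; chains of \code{group_b} are perturbed.
#' @param schedule Perturbation schedule from [make_perturbation_schedule()],
#'   or any data frame with columns \code{rotation_deg} and
#'   \code{translation_ang}.
#' @param seed Integer seed for the perturbation axes and directions.
#' @return List with \code{models} (named list of \code{cl_structure};
#'   \code{decoy_000} is the native) and \code{rmsd} (named numeric vector of
#'   superposed alpha-carbon RMSDs to the native, Angstrom).
#' @export
make_decoys <- function(native, spec,
                        schedule = make_perturbation_schedule(), seed = 1) {
  stopifnot(inherits(native, "cl_structure"), inherits(spec, "cl_partners"),
            is.data.frame(schedule),
            all(c("rotation_deg", "translation_ang") %in% names(schedule)))
  nd <- nrow(schedule)
  with_seed(derive_seed(seed, 2L), {
    models <- vector("list", nd + 1L)
    ids <- sprintf("decoy_%03d", 0:nd)
    native_d <- new_structure(ids[1L], native$atoms)
    models[[1L]] <- native_d
    for (i in seq_len(nd)) {
      axis <- stats::rnorm(3L)
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      rot <- rotation_about_axis(axis, schedule$rotation_deg[i])
      m <- transform_partner(native, spec$group_b, rot,
                             dir * schedule$translation_ang[i])
      models[[i + 1L]] <- new_structure(ids[i + 1L], m$atoms)
    }
    names(models) <- ids
    rmsd <- vapply(models, complex_rmsd, numeric(1L), reference = native)
    list(models = models, rmsd = rmsd)
  })
}

#' Generate wrong-site contact decoys
#'
#' Emulates the globally wrong poses a rigid-body docking run with a
#' randomized second partner produces: partner B is given a random
#' orientation (rotation of 60-180 degrees about a random axis through its
#' centroid) and then slid along a random direction from partner A's centroid
#' until the partners are just in contact (shortest heavy-atom gap close to
#' \code{gap}). Such poses remain docked but bury the wrong surfaces, so the
#' distances of the true interface residues to the partner are strongly
#' perturbed -- the disagreement the labeling score term detects.
#'
#' A sparse distance pattern cannot reject every wrong pose: occasionally a
#' random placement reproduces the native residue-to-partner distances (for
#' example a mirror-like approach to the same interface), and no
#' distance-derived restraint could tell the two apart. Because this
#' generator exists to plant a detectable signal, candidate poses that leave
#' fewer than \code{min_disrupted} residues with a distance change of at
#' least \code{min_disruption} Angstrom are resampled (up to 50 draws, then
#' the most disruptive candidate is kept).
#'
#' @param native A \code{cl_structure}.
#' @param spec A \code{cl_partners}; \code{group_b} chains are moved.
#' @param n Number of decoys to generate.
#' @param seed Integer seed.
#' @param gap Target shortest heavy-atom gap at contact, Angstrom.
#' @param min_disruption Residue-to-partner distance change (Angstrom) that
#'   counts as disrupted.
#' @param min_disrupted Minimum number of disrupted residues per decoy.
#' @return List with \code{models} (named list, ids \code{wrong_001}, ...)
#'   and \code{rmsd} (superposed alpha-carbon RMSD to the native).
#' @export
make_wrongsite_decoys <- function(native, spec, n, seed = 1, gap = 4,
                                  min_disruption = 20, min_disrupted = 3) {
  stopifnot(inherits(native, "cl_structure"), inherits(spec, "cl_partners"),
            n >= 1L)
  at <- native$atoms
  a_xyz <- as.matrix(at[at$chain %in% spec$group_a, c("x", "y", "z")])
  b_sel <- at$chain %in% spec$group_b
  b_xyz <- as.matrix(at[b_sel, c("x", "y", "z")])
  a_ctr <- colMeans(a_xyz)
  b_ctr <- colMeans(b_xyz)
  res <- structure_residues(native)
  res <- res[res$chain %in% c(spec$group_a, spec$group_b), , drop = FALSE]
  d_native <- interface_distances(native, spec, res)

  propose <- function() {
    rot <- rotation_about_axis(stats::rnorm(3L), stats::runif(1L, 60, 180))
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    b_rot <- sweep(sweep(b_xyz, 2L, b_ctr) %*% rot, 2L, b_ctr, "+")
    # place the reoriented partner along `dir` from A's centroid at the
    # exact outermost contact point: each atom pair's distance along the
    # line is sqrt(s^2 - 2 s (c.dir) + |c|^2), so the largest s putting any
    # pair at `gap` is the max over the larger quadratic roots
    b_cen <- sweep(b_rot, 2L, colMeans(b_rot))
    cd <- numeric(0); cc <- numeric(0)
    for (k in seq_len(nrow(b_cen))) {
      cmat <- sweep(a_xyz, 2L, a_ctr + b_cen[k, ], "-")
      cd <- c(cd, as.numeric(cmat %*% dir))
      cc <- c(cc, rowSums(cmat^2))
    }
    disc <- cd^2 - cc + gap^2
    real <- disc >= 0
    s <- if (any(real)) max(cd[real] + sqrt(disc[real]))
         else cd[which.min(cc - cd^2)]  # line misses: closest approach
    sweep(b_cen, 2L, a_ctr + s * dir, "+")
  }

  with_seed(derive_seed(seed, 5L), {
    models <- vector("list", n)
    ids <- sprintf("wrong_%03d", seq_len(n))
    for (i in seq_len(n)) {
      best <- NULL
      best_score <- -1L
      for (attempt in 1:50) {
        b_try <- propose()
        new_at <- at
        new_at[b_sel, c("x", "y", "z")] <- b_try
        cand <- new_structure(ids[i], new_at)
        d_cand <- interface_distances(cand, spec, res)
        n_disrupted <- sum(abs(d_cand - d_native) >= min_disruption)
        if (n_disrupted > best_score) {
          best <- cand
          best_score <- n_disrupted
        }
        if (n_disrupted >= min_disrupted) break
      }
      models[[i]] <- best
    }
    names(models) <- ids
    rmsd <- vapply(models, complex_rmsd, numeric(1L), reference = native)
    list(models = models, rmsd = rmsd)
  })
}

#' Simulate a differential-labeling table from a structure
#'
#' Forward-simulates the linear relationship the rescoring method assumes:
#' each selected residue's modification change is set to
#' \code{slope * interface_distance + intercept} plus Gaussian noise, capped
#' at 100 percent (full protection). Degrees of modification are back-solved
#' with \code{M_unbound = 1}, so \code{M_bound = 1 - change / 100}.
#'
#' @param native A \code{cl_structure} (distances are taken from it).
#' @param spec A \code{cl_partners}.
#' @param calib A \code{cl_calibration} providing slope and intercept.
#' @param noise_sd Gaussian noise on the change, in percent (>= 0).
#' @param seed Integer seed.
#' @param complex_id Label written into the table.
#' @param residues Optional data frame (\code{chain}, \code{resno}) of
#'   residues to label; default: every residue of both partners.
#' @return Labeling data frame in the [load_labeling_table()] schema, plus
#'   \code{modification_change} and \code{interface_distance} columns.
#' @export
simulate_labeling <- function(native, spec, calib = calibration_model(),
                              noise_sd = 5, seed = 1,
                              complex_id = "synthetic", residues = NULL) {
  stopifnot(inherits(native, "cl_structure"), inherits(spec, "cl_partners"),
            inherits(calib, "cl_calibration"), noise_sd >= 0)
  res <- structure_residues(native)
  res <- res[res$chain %in% c(spec$group_a, spec$group_b), , drop = FALSE]
  if (!is.null(residues)) {
    keep <- paste(res$chain, res$resno) %in%
      paste(residues$chain, residues$resno)
    res <- res[keep, , drop = FALSE]
  }
  stopifnot(nrow(res) >= 2L)
  d <- interface_distances(native, spec, res)
  with_seed(derive_seed(seed, 3L), {
    change <- predict_modification_change(d, calib) +
      stats::rnorm(nrow(res), 0, noise_sd)
    change <- pmin(change, 100)
    data.frame(complex_id = complex_id, chain = res$chain,
               residue_number = res$resno, residue_name = res$resid,
               measure_kind = "rate", M_unbound = 1,
               M_bound = 1 - change / 100,
               modification_change = change, interface_distance = d,
               stringsAsFactors = FALSE)
  })
}

#' Surrogate interface scores for a decoy ensemble
#'
#' Emulates an externally computed interface energy as a linear function of
#' each decoy's true RMSD plus Gaussian noise:
#' \code{isc = base + isc_signal * rmsd + noise}. A positive signal makes the
#' energy informative (lower for near-native poses); zero or negative signal
#' with noise yields the misleading-energy scenario in which energy-only
#' ranking picks a wrong pose while labeling-guided rescoring recovers the
#' native.
#'
#' @param rmsd Named numeric vector of decoy RMSDs (names are model ids).
#' @param isc_signal Energy units per Angstrom of RMSD.
#' @param isc_noise_sd Gaussian noise SD, energy units.
#' @param seed Integer seed.
#' @param base Baseline energy (default -30).
#' @return Data frame with columns \code{model_id}, \code{isc}.
#' @export
surrogate_isc <- function(rmsd, isc_signal = 0, isc_noise_sd = 3, seed = 1,
                          base = -30) {
  stopifnot(is.numeric(rmsd), length(rmsd) >= 1L, !is.null(names(rmsd)))
  with_seed(derive_seed(seed, 4L), {
    data.frame(model_id = names(rmsd),
               isc = base + isc_signal * unname(rmsd) +
                 stats::rnorm(length(rmsd), 0, isc_noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic rescoring scenario
#'
#' Bundles the generators into one seeded scenario: a toy native complex, a
#' decoy ensemble, a simulated labeling table derived from the native
#' interface, and surrogate interface scores. The ensemble mirrors what a
#' rigid-body docking run with a randomized second partner produces: the
#' native, a small near-native funnel (gentle rigid perturbations, RMSD under
#' about 1.5 Angstrom), and wrong-site contact poses ([make_wrongsite_decoys()])
#' for the remainder. The default surrogate energy is misleading -- a mildly
#' negative signal of -0.2 energy units per Angstrom of RMSD with noise SD
#' 1.5, so the energy's global minimum falls on a wrong pose -- while the
#' labeling table carries genuine interface information (noise SD 5 percent
#' around the calibration line).
#'
#' @param seed Integer seed; fully determines the scenario.
#' @param n_residues_per_chain Residues per chain of the toy native.
#' @param n_decoys Perturbed decoys (native is added on top as
#'   \code{decoy_000}).
#' @param n_near Near-native decoys within \code{n_decoys}.
#' @param labeling_noise_sd Labeling noise, percent.
#' @param isc_noise_sd Interface-energy noise, energy units.
#' @param isc_signal Interface-energy slope vs RMSD, energy units per
#'   Angstrom.
#' @param calib Calibration used both to simulate and to rescore.
#' @param params Scoring parameters.
#' @return List of class \code{cl_scenario} with elements \code{native},
#'   \code{spec}, \code{models}, \code{rmsd}, \code{labeling}, \code{isc},
#'   \code{calib}, \code{params}, \code{seed}.
#' @export
make_scenario <- function(seed = 1, n_residues_per_chain = 10, n_decoys = 40,
                          n_near = 3, labeling_noise_sd = 5,
                          isc_noise_sd = 1.5, isc_signal = -0.2,
                          calib = calibration_model(),
                          params = scoring_params()) {
  stopifnot(n_decoys >= n_near + 1L, n_near >= 0L)
  native <- make_toy_complex(n_residues_per_chain, seed = seed)
  spec <- parse_partner_spec("A_B", native)
  near_schedule <- data.frame(rotation_deg = 2 * seq_len(n_near),
                              translation_ang = 0.3 * seq_len(n_near))
  near <- make_decoys(native, spec, near_schedule, seed = seed)
  wrong <- make_wrongsite_decoys(native, spec, n = n_decoys - n_near,
                                 seed = seed)
  models <- c(near$models, wrong$models)
  rmsd <- c(near$rmsd, wrong$rmsd)
  ids <- sprintf("decoy_%03d", seq_along(models) - 1L)
  names(models) <- ids
  names(rmsd) <- ids
  for (i in seq_along(models)) models[[i]]$model_id <- ids[i]
  labeling <- simulate_labeling(native, spec, calib,
                                noise_sd = labeling_noise_sd, seed = seed)
  isc <- surrogate_isc(rmsd, isc_signal = isc_signal,
                       isc_noise_sd = isc_noise_sd, seed = seed)
  structure(list(native = native, spec = spec, models = models,
                 rmsd = rmsd, labeling = labeling, isc = isc,
                 calib = calib, params = params, seed = as.integer(seed)),
            class = "cl_scenario")
}

#' Rescore a synthetic scenario and evaluate the top models
#'
#' Runs [rescore_ensemble()] on a scenario and reports the RMSD of the
#' top-ranked model under the combined labeling-guided score and under the
#' interface energy alone.
#'
#' @param scenario A \code{cl_scenario} from [make_scenario()].
#' @return List with \code{scores} (ranked score table),
#'   \code{top_rmsd_cl} and \code{top_rmsd_isc} (Angstrom), and
#'   \code{top_id_cl}, \code{top_id_isc}.
#' @export
evaluate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "cl_scenario"))
  scores <- rescore_ensemble(scenario$models, scenario$isc, scenario$spec,
                             scenario$labeling, scenario$calib,
                             scenario$params)
  ord_isc <- order(scores$isc, scores$model_id, method = "radix")
  top_cl <- scores$model_id[scores$rank == 1L]
  top_isc <- scores$model_id[ord_isc[1L]]
  list(scores = scores,
       top_rmsd_cl = unname(scenario$rmsd[top_cl]),
       top_rmsd_isc = unname(scenario$rmsd[top_isc]),
       top_id_cl = top_cl, top_id_isc = top_isc)
}
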