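#' Read a PDB coordinate file into a heavy-atom structure
#'
#' Parses standard PDB ATOM records (via \pkg{bio3d}) and reduces them to the
#' polymer heavy-atom model used throughout the package: hydrogens and
#' deuteriums are removed, HETATM records (waters, ligands, ions) are dropped,
#' and alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by file order). Only the first MODEL of a multi-model file is
#' read; docked decoys are single-model.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param model_id Text label for the structure; defaults to the file stem.
#' @return An object of class \code{cl_structure}: a list with
#'   \code{model_id}, \code{chains} (chain identifiers in file order) and
#'   \code{atoms}, a data frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z} (coordinates in Angstrom).
#' @export
#' @examples
#' pdb <- write_structure_pdb(make_toy_complex(6, seed = 1),
#'                            tempfile(fileext = ".pdb"))
#' s <- parse_structure(pdb)
#' s$chains
parse_structure <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not read PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no protein ATOM records in '", path, "'", call. = FALSE)

  # element: trust the element column where present, else derive from the
  # atom name (strip leading digits, take the first letter)
  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  fallback <- toupper(substr(gsub("^[0-9]+", "", trimws(at$elety)), 1L, 1L))
  elem[!nzchar(elem)] <- fallback[!nzchar(elem)]
  at$element <- elem
  n_h <- sum(elem %in% c("H", "D"))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no heavy atoms left after filtering '", path, "'", call. = FALSE)

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o[is.na(at$o)] <- 1

  # resolve altlocs: per (chain, resno, insert, atom name) keep the
  # highest-occupancy conformer, first-encountered on ties
  if (any(nzchar(at$alt))) {
    at$.row <- seq_len(nrow(at))
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -at$o, at$.row, method = "radix")
    keep <- !duplicated(key[ord])
    dropped <- nrow(at) - sum(keep)
    at <- at[sort(at$.row[ord][keep]), , drop = FALSE]
    at$.row <- NULL
    if (dropped > 0L)
      message(sprintf("parse_structure('%s'): dropped %d alternate-location atom(s)",
                      basename(path), dropped))
  }
  if (n_h > 0L)
    message(sprintf("parse_structure('%s'): removed %d hydrogen atom(s)",
                    basename(path), n_h))

  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      insert = as.character(at$insert),
                      resid = as.character(at$resid),
                      elety = trimws(as.character(at$elety)),
                      element = as.character(at$element),
                      x = as.numeric(at$x), y = as.numeric(at$y),
                      z = as.numeric(at$z), stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  new_structure(model_id, atoms)
}

# internal constructor; validates the cl_structure invariants
new_structure <- function(model_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  stopifnot(all(is.finite(c(atoms$x, atoms$y, atoms$z))))
  structure(list(model_id = as.character(model_id),
                 chains = unique(atoms$chain),
                 atoms = atoms),
            class = "cl_structure")
}

#' @export
print.cl_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat(sprintf("cl_structure '%s': %d chain(s) [%s], %d residues, %d heavy atoms\n",
              x$model_id, length(x$chains), paste(x$chains, collapse = ","),
              nres, nrow(x$atoms)))
  invisible(x)
}

# residue key used for identity lookups
residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
}

#' List the residues of a structure
#'
#' @param structure A \code{cl_structure}.
#' @return Data frame with one row per residue: \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, in atom order.
#' @export
structure_residues <- function(structure) {
  stopifnot(inherits(structure, "cl_structure"))
  at <- structure$atoms
  unique(at[, c("chain", "resno", "insert", "resid")])
}

#' Parse a docking-partner specification
#'
#' A partner spec names the two rigid bodies of a docking case as two groups
#' of single-character chain identifiers separated by one underscore, e.g.
#' \code{"A_G"}, \code{"AB_CD"} or \code{"ABCD_EFGH"}. Chains present in the
#' structure but named in neither group are ignored in distance computations.
#'
#' @param spec Specification string.
#' @param structure A \code{cl_structure} whose chains the spec must name.
#' @return An object of class \code{cl_partners}: list with character vectors
#'   \code{group_a} and \code{group_b}.
#' @export
#' @examples
#' s <- make_toy_complex(6, seed = 1)
#' parse_partner_spec("A_B", s)
parse_partner_spec <- function(spec, structure) {
  stopifnot(is.character(spec), length(spec) == 1L)
  stopifnot(inherits(structure, "cl_structure"))
  parts <- strsplit(spec, "", fixed = TRUE)[[1L]]
  if (sum(parts == "_") != 1L)
    stop("partner spec must contain exactly one underscore: '", spec, "'",
         call. = FALSE)
  halves <- strsplit(spec, "_", fixed = TRUE)[[1L]]
  group_a <- strsplit(halves[1L], "", fixed = TRUE)[[1L]]
  group_b <- if (length(halves) >= 2L)
    strsplit(halves[2L], "", fixed = TRUE)[[1L]] else character(0L)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both partner groups must be non-empty: '", spec, "'", call. = FALSE)
  both <- c(group_a, group_b)
  dup <- unique(both[duplicated(both)])
  if (length(dup))
    stop("chain(s) assigned to both partners: ", paste(dup, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(both, structure$chains)
  if (length(unknown))
    stop("chain(s) not present in structure '", structure$model_id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(group_a = group_a, group_b = group_b, spec = spec),
            class = "cl_partners")
}

#' @export
print.cl_partners <- function(x, ...) {
  cat(sprintf("docking partners: {%s} vs {%s}\n",
              paste(x$group_a, collapse = ","),
              paste(x$group_b, collapse = ",")))
  invisible(x)
}

#' Shortest heavy-atom distance from a residue to the opposite partner
#'
#' The interface distance of a residue is the minimum Euclidean distance
#' between any of its heavy atoms and any heavy atom of the opposite docking
#' partner. Chains outside the partner spec do not contribute.
#'
#' @param structure A \code{cl_structure}.
#' @param spec A \code{cl_partners} from [parse_partner_spec()].
#' @param chain Chain identifier of the target residue.
#' @param resno Residue number (integer).
#' @param insert Insertion code; \code{NULL} (default) requires the residue
#'   number to be unambiguous within the chain, otherwise a lookup error is
#'   raised rather than a silent pick.
#' @return Interface distance in Angstrom.
#' @export
interface_distance <- function(structure, spec, chain, resno, insert = NULL) {
  stopifnot(inherits(structure, "cl_structure"),
            inherits(spec, "cl_partners"))
  at <- structure$atoms
  sel <- at$chain == chain & at$resno == resno
  if (!is.null(insert)) sel <- sel & at$insert == insert
  res_at <- at[sel, , drop = FALSE]
  if (nrow(res_at) == 0L)
    stop(sprintf("residue %s%d%s not found in '%s'", chain, resno,
                 if (is.null(insert)) "" else insert, structure$model_id),
         call. = FALSE)
  if (is.null(insert) && length(unique(res_at$insert)) > 1L)
    stop(sprintf("residue %s%d matches multiple insertion codes in '%s'",
                 chain, resno, structure$model_id), call. = FALSE)
  in_a <- chain %in% spec$group_a
  in_b <- chain %in% spec$group_b
  if (!in_a && !in_b)
    stop("chain '", chain, "' is in neither partner group", call. = FALSE)
  opp_chains <- if (in_a) spec$group_b else spec$group_a
  opp_at <- at[at$chain %in% opp_chains, , drop = FALSE]
  if (nrow(opp_at) == 0L)
    stop("opposite partner has no atoms", call. = FALSE)
  min_pair_dist(as.matrix(res_at[, c("x", "y", "z")]),
                as.matrix(opp_at[, c("x", "y", "z")]))
}

# exact minimum Euclidean distance between two point sets (n x 3, m x 3)
min_pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Classify a residue as interface or non-interface by distance
#'
#' A residue belongs to the binding interface when its shortest heavy-atom
#' distance to the partner is less than or equal to the cutoff (boundary
#' inclusive; 10 Angstrom by default convention).
#'
#' @param distance Interface distance(s) in Angstrom; must be non-negative.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Logical vector, \code{TRUE} where \code{distance <= cutoff}.
#' @export
is_interface_residue <- function(distance, cutoff = 10) {
  stopifnot(is.numeric(distance), is.numeric(cutoff), cutoff > 0)
  if (any(distance < 0, na.rm = TRUE))
    stop("interface distance cannot be negative", call. = FALSE)
  distance <= cutoff
}

#' Interface distances for a set of residues
#'
#' Vector convenience wrapper around [interface_distance()].
#'
#' @param structure A \code{cl_structure}.
#' @param spec A \code{cl_partners}.
#' @param residues Data frame with columns \code{chain} and \code{resno}
#'   (optional \code{insert}).
#' @return Numeric vector of distances, one per row of \code{residues}.
#' @export
interface_distances <- function(structure, spec, residues) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "resno") %in% names(residues)))
  vapply(seq_len(nrow(residues)), function(i) {
    interface_distance(structure, spec, residues$chain[i],
                       residues$resno[i],
                       if ("insert" %in% names(residues))
                         residues$insert[i] else NULL)
  }, numeric(1L))
}
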