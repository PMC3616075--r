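centroid_of <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

#' Active-site opening distance time series
#'
#' Per frame, the Euclidean distance between the geometric centres
#' (unweighted means) of the CA atoms of the Walker A motif of one monomer
#' and the C-motif of the opposing monomer, for both composite sites. No
#' superposition is applied: the distances are internal to each frame, so
#' the series is invariant under global rigid motion. This is the
#' per-site gauge of active-site closure: `site_nuc` is the
#' nucleotide-bound site, `site_apo` the empty one.
#'
#' @param traj a `trajectory3d`.
#' @param scheme a [residue_scheme()].
#' @return data.frame with columns `frame`, `time_ps`, `site_nuc`,
#'   `site_apo` (Angstrom).
#' @export
opening_distance_series <- function(traj, scheme = residue_scheme()) {
  sites <- paired_site_selections(traj$topology, scheme)
  one <- function(f) {
    fx <- frame_xyz(traj, f)
    vapply(sites, function(site) {
      sqrt(sum((centroid_of(fx, site$walker_a$indices) -
                  centroid_of(fx, site$c_motif$indices))^2))
    }, numeric(1))
  }
  vals <- t(vapply(seq_len(n_frames(traj)), one, numeric(2)))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
             site_nuc = vals[, 1], site_apo = vals[, 2])
}

#' Opening distances of a single structure
#' @param struct a `structure3d`.
#' @param scheme a [residue_scheme()].
#' @return named numeric vector `c(site_nuc =, site_apo =)` in Angstrom.
#' @export
opening_distances <- function(struct, scheme = residue_scheme()) {
  sites <- paired_site_selections(struct, scheme)
  vapply(sites, function(site) {
    sqrt(sum((centroid_of(struct$xyz, site$walker_a$indices) -
                centroid_of(struct$xyz, site$c_motif$indices))^2))
  }, numeric(1))
}

#' Minimum cross-pair distance time series
#'
#' Per frame, the minimum Euclidean distance over all pairs (a in selA,
#' b in selB). Selections may contain any atoms (sidechain, ligand),
#' not just CA.
#'
#' @param traj a `trajectory3d`.
#' @param selA,selB non-empty `atom_selection`s.
#' @param label series label.
#' @return data.frame with columns `frame`, `time_ps`, `value` (Angstrom)
#'   and attribute `label`.
#' @export
pair_min_distance_series <- function(traj, selA, selB, label = "min_distance") {
  check_selection(traj$topology, selA); check_selection(traj$topology, selB)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fx <- frame_xyz(traj, f)
    a <- fx[selA$indices, , drop = FALSE]
    b <- fx[selB$indices, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
                    value = vals)
  attr(out, "label") <- label
  out
}

# atoms of ligand residues matching name table; internal
ligand_atom_indices <- function(struct, atom_names, ligand_resnames) {
  which(struct$atoms$resid %in% ligand_resnames &
          struct$atoms$elety %in% atom_names)
}

#' C-motif serine hydroxyl to nucleotide beta-phosphate distance series
#'
#' Per frame, the minimum distance from the C-motif serine hydroxyl oxygen
#' (atom OG of the first C-motif residue) to any beta-phosphate oxygen of
#' the bound nucleotide. The "proximal" oxygen is resolved per frame as
#' the minimum rather than a fixed atom. If serines of both monomers
#' carry an OG, the engaged one (smallest first-frame distance) is used
#' and reported via the `chain` attribute.
#'
#' @param traj a `trajectory3d`.
#' @param scheme a [residue_scheme()].
#' @param ligand_resnames residue names recognised as the nucleotide.
#' @param beta_oxygens beta-phosphate oxygen atom names (PDB chemical
#'   component conventions).
#' @return data.frame with columns `frame`, `time_ps`, `value` (Angstrom);
#'   attributes `chain` (serine chain used) and `label`.
#' @export
serine_phosphate_series <- function(traj, scheme = residue_scheme(),
                                    ligand_resnames = c("ADP", "ATP", "AGS"),
                                    beta_oxygens = c("O1B", "O2B", "O3B")) {
  at <- traj$topology$atoms
  ser_res <- ranges_to_residues(scheme$c_motif)[1]
  og <- which(at$resno == ser_res & at$elety == "OG")
  lig <- ligand_atom_indices(traj$topology, beta_oxygens, ligand_resnames)
  missing <- character(0)
  if (!length(og)) missing <- c(missing, sprintf("OG of residue %d", ser_res))
  if (!length(lig)) missing <- c(missing,
                                 paste("beta-phosphate oxygens", paste(beta_oxygens, collapse = "/")))
  if (length(missing))
    stop("required atoms absent: ", paste(missing, collapse = "; "))
  ligsel <- atom_selection(lig, "beta-phosphate O")
  per_chain <- lapply(og, function(i)
    pair_min_distance_series(traj, atom_selection(i, "serine OG"), ligsel))
  j <- which.min(vapply(per_chain, function(d) d$value[1], numeric(1)))
  out <- per_chain[[j]]
  attr(out, "chain") <- at$chain[og[j]]
  attr(out, "label") <- "serine_OG_beta_phosphate"
  out
}

#' D-loop carbonyl to inorganic-phosphate contact distance
#'
#' Minimum distance from the backbone carbonyl oxygen (atom O) of the
#' D-loop residue (A175 in MJ0796 numbering) of either monomer to any
#' oxygen of an inorganic phosphate in the structure. In the ADP+Pi-bound
#' MJ0796 (E171Q) crystal structure this trans-monomer hydrogen bond is
#' 2.7 Angstrom; the proximity itself identifies which Pi oxygen is the
#' hydroxyl. The atom pair attaining the minimum is reported in the
#' attributes.
#'
#' @param struct a `structure3d` (e.g. read from PDB entry 3TIF).
#' @param scheme a [residue_scheme()].
#' @param phosphate_resnames residue names recognised as inorganic phosphate.
#' @return minimum distance in Angstrom, with attributes `chain` (D-loop
#'   monomer) and `atom` (phosphate oxygen name).
#' @export
dloop_phosphate_distance <- function(struct, scheme = residue_scheme(),
                                     phosphate_resnames = c("PO4", "PI", "2HP", "PO3")) {
  at <- struct$atoms
  oc <- which(at$resno == scheme$d_loop_residue & at$elety == "O" &
                at$chain %in% c(scheme$nucleotide_monomer, scheme$apo_monomer))
  if (!length(oc)) stop("no backbone O of D-loop residue ", scheme$d_loop_residue)
  po <- which(at$resid %in% phosphate_resnames & at$elesy == "O")
  if (!length(po)) stop("no inorganic-phosphate oxygens (residues ",
                        paste(phosphate_resnames, collapse = "/"), ")")
  a <- struct$xyz[oc, , drop = FALSE]
  b <- struct$xyz[po, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  k <- arrayInd(which.min(d2), dim(d2))
  out <- sqrt(max(0, min(d2)))
  attr(out, "chain") <- at$chain[oc[k[1]]]
  attr(out, "atom") <- at$elety[po[k[2]]]
  out
}
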