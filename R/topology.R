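#' NBD residue scheme
#'
#' Encodes the subdomain and motif residue ranges of an ABC transporter
#' nucleotide-binding domain, per monomer, with 1-based inclusive residue
#' ranges. Defaults are the MJ0796 numbering: core subdomain 1-90 and
#' 164-228 (the RecA-like lobe, excluding the mobile 7-residue C-terminal
#' tail 229-235), helical subdomain 94-161 (the ABC-specific lobe), the
#' Q-loop (91-93) and Pro-loop (161-163) assigned to neither subdomain, and
#' the alpha3-4 loop (112-116) excluded from helical RMSD but not from
#' domain membership. Walker A centre residues 43-46 (GKST) and C-motif
#' centre residues 147-150 (SGGQ) define the active-site opening gauge;
#' D-loop residue 175 contacts the trans site. Chains: the
#' nucleotide-bound monomer is "A", the apo monomer "B".
#'
#' Ranges are lists of `c(lo, hi)` pairs. Two helical selections are
#' distinguished: `helical_domain` (94-161) for hinge/domain work and
#' `helical_rmsd` (94-111, 117-161) for RMSD, which excludes the highly
#' mobile alpha3-4 loop.
#'
#' @param core,helical_rmsd,helical_domain,q_loop,pro_loop,a34_loop,c_term_tail,walker_a,c_motif
#'   residue ranges (list of `c(lo, hi)` integer pairs).
#' @param d_loop_residue single residue number of the D-loop alanine.
#' @param nucleotide_monomer,apo_monomer chain identifiers.
#' @return An object of class `residue_scheme`.
#' @export
residue_scheme <- function(core = list(c(1, 90), c(164, 228)),
                           helical_rmsd = list(c(94, 111), c(117, 161)),
                           helical_domain = list(c(94, 161)),
                           q_loop = list(c(91, 93)),
                           pro_loop = list(c(161, 163)),
                           a34_loop = list(c(112, 116)),
                           c_term_tail = list(c(229, 235)),
                           walker_a = list(c(43, 46)),
                           c_motif = list(c(147, 150)),
                           d_loop_residue = 175,
                           nucleotide_monomer = "A",
                           apo_monomer = "B") {
  rngs <- list(core = core, helical_rmsd = helical_rmsd,
               helical_domain = helical_domain, q_loop = q_loop,
               pro_loop = pro_loop, a34_loop = a34_loop,
               c_term_tail = c_term_tail, walker_a = walker_a,
               c_motif = c_motif)
  for (nm in names(rngs)) {
    for (r in rngs[[nm]]) {
      if (length(r) != 2L || r[1] > r[2])
        stop("malformed range in '", nm, "': ranges are c(lo, hi) with lo <= hi")
    }
  }
  res <- lapply(rngs, ranges_to_residues)
  if (!all(res$walker_a %in% res$core))
    stop("walker_a centre must lie within the core subdomain")
  if (!all(res$c_motif %in% res$helical_domain))
    stop("c_motif centre must lie within the helical subdomain")
  if (any(res$a34_loop %in% res$helical_rmsd))
    stop("helical_rmsd must exclude the a34_loop")
  if (any(res$c_term_tail %in% res$core))
    stop("core must exclude the C-terminal tail")
  structure(c(rngs, list(d_loop_residue = as.integer(d_loop_residue),
                         nucleotide_monomer = nucleotide_monomer,
                         apo_monomer = apo_monomer)),
            class = "residue_scheme")
}

#' @export
print.residue_scheme <- function(x, ...) {
  fmt <- function(rr) paste(vapply(rr, function(r) paste(r, collapse = "-"),
                                   character(1)), collapse = ", ")
  cat("<residue_scheme>\n")
  for (nm in c("core", "helical_rmsd", "helical_domain", "q_loop", "pro_loop",
               "a34_loop", "c_term_tail", "walker_a", "c_motif"))
    cat(sprintf("  %-15s %s\n", nm, fmt(x[[nm]])))
  cat(sprintf("  %-15s %d\n", "d_loop_residue", x$d_loop_residue))
  cat(sprintf("  monomers: nucleotide-bound '%s', apo '%s'\n",
              x$nucleotide_monomer, x$apo_monomer))
  invisible(x)
}

#' Expand residue ranges to a residue-number vector
#' @param ranges list of `c(lo, hi)` pairs (or a bare numeric pair).
#' @return sorted integer vector of residue numbers.
#' @export
ranges_to_residues <- function(ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  sort(unique(unlist(lapply(ranges, function(r) seq.int(r[1], r[2])))))
}

#' Build an atom selection
#' @param indices ascending unique atom indices.
#' @param label selection label.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(indices, label = "") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (is.unsorted(indices)) stop("selection indices must be ascending")
  structure(list(label = label, indices = indices), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

#' Select C-alpha atoms of given residues on one chain
#'
#' Returns the CA atoms of the listed residues that are present in the
#' structure, in residue order. Missing residues are tolerated with a
#' message reporting the count (crystal structures have gaps).
#'
#' @param struct a `structure3d`.
#' @param chain chain identifier.
#' @param ranges residue ranges (list of `c(lo, hi)`) or residue-number vector.
#' @param label optional selection label.
#' @return an `atom_selection`.
#' @export
select_calpha <- function(struct, chain, ranges, label = NULL) {
  at <- struct$atoms
  if (!chain %in% at$chain) stop("chain '", chain, "' not present in structure")
  want <- if (is.list(ranges)) ranges_to_residues(ranges) else sort(unique(as.integer(ranges)))
  idx <- which(at$chain == chain & at$elety == "CA" & at$resno %in% want)
  idx <- idx[order(at$resno[idx])]
  if (length(idx) == 0L)
    stop("empty selection: no CA atoms for chain '", chain, "' residues ",
         paste(range(want), collapse = "-"))
  n_missing <- length(want) - length(idx)
  if (n_missing > 0L)
    message(n_missing, " of ", length(want), " requested residues absent on chain '",
            chain, "'")
  if (is.null(label)) label <- sprintf("chain %s CA (%d residues)", chain, length(idx))
  atom_selection(sort(idx), label)
}

#' Paired active-site selections for the two composite sites
#'
#' The NBD sandwich dimer has two composite active sites: the C-motif of
#' one monomer engages nucleotide bound at the Walker A motif of the other.
#' `site_nuc` pairs the Walker A of the nucleotide-bound monomer with the
#' C-motif of the apo monomer; `site_apo` pairs the Walker A of the apo
#' monomer with the C-motif of the nucleotide-bound monomer. Each
#' selection must resolve all four motif CA atoms.
#'
#' @param struct a `structure3d` containing both chains.
#' @param scheme a [residue_scheme()].
#' @return list of two sites, each `list(walker_a =, c_motif =)` of
#'   `atom_selection`s.
#' @export
paired_site_selections <- function(struct, scheme = residue_scheme()) {
  chains <- c(scheme$nucleotide_monomer, scheme$apo_monomer)
  for (ch in chains)
    if (!ch %in% struct$atoms$chain)
      stop("chain '", ch, "' not present in structure")
  motif <- function(chain, ranges, site, what) {
    want <- ranges_to_residues(ranges)
    sel <- suppressMessages(tryCatch(
      select_calpha(struct, chain, ranges,
                    label = sprintf("%s %s (chain %s)", site, what, chain)),
      error = function(e) NULL))
    if (is.null(sel) || length(sel$indices) != length(want))
      stop(site, ": incomplete ", what, " motif on chain '", chain, "'")
    sel
  }
  list(
    site_nuc = list(
      walker_a = motif(scheme$nucleotide_monomer, scheme$walker_a, "site_nuc", "Walker A"),
      c_motif = motif(scheme$apo_monomer, scheme$c_motif, "site_nuc", "C-motif")),
    site_apo = list(
      walker_a = motif(scheme$apo_monomer, scheme$walker_a, "site_apo", "Walker A"),
      c_motif = motif(scheme$nucleotide_monomer, scheme$c_motif, "site_apo", "C-motif")))
}

#' Standard scheme-derived C-alpha selections
#'
#' Convenience accessor for the selections the analysis battery uses:
#' `"all"` (all CA of both monomers), `"monomer"` (all CA of one chain),
#' `"core"`, `"helical_rmsd"`, `"helical_domain"` (per chain).
#'
#' @param struct a `structure3d`.
#' @param scheme a [residue_scheme()].
#' @param what one of `"all"`, `"monomer"`, `"core"`, `"helical_rmsd"`,
#'   `"helical_domain"`.
#' @param chain chain id (ignored for `"all"`).
#' @return an `atom_selection`.
#' @export
scheme_selection <- function(struct, scheme = residue_scheme(),
                             what = c("all", "monomer", "core", "helical_rmsd",
                                      "helical_domain"),
                             chain = NULL) {
  what <- match.arg(what)
  if (what == "all") {
    idx <- which(struct$atoms$elety == "CA" &
                   struct$atoms$chain %in% c(scheme$nucleotide_monomer, scheme$apo_monomer))
    if (!length(idx)) stop("no CA atoms on the scheme's chains")
    return(atom_selection(idx, "all CA"))
  }
  if (is.null(chain)) stop("chain is required for '", what, "'")
  if (what == "monomer") {
    idx <- which(struct$atoms$elety == "CA" & struct$atoms$chain == chain)
    if (!length(idx)) stop("no CA atoms on chain '", chain, "'")
    return(atom_selection(idx, sprintf("monomer %s CA", chain)))
  }
  select_calpha(struct, chain, scheme[[what]],
                label = sprintf("%s (chain %s)", what, chain))
}
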