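# Small-molecule ligand scoring: element-labeled molecular graphs, symmetry
# enumeration by graph isomorphism, and pocket-aligned RMSD.
#
# Ligand atoms carry no canonical order, so the model/reference atom
# correspondence is found by matching their covalent-bond graphs; when a
# molecule is symmetric there are several isomorphisms and the reported
# RMSD is the minimum over all of them. Only the pocket-aligned LRMSD is
# reported for small molecules: fnat/iRMSD and the combined score are not
# defined for them.

#' Build the covalent-bond graph of a ligand
#'
#' An edge joins atoms i and j when their distance does not exceed the sum
#' of their single-bond covalent radii plus a tolerance (0.4 Angstrom by
#' default, the usual bond-perception slack). Hydrogens were already dropped
#' at parse time, so the graph is over heavy atoms.
#'
#' @param ligand A `SMALL_MOLECULE` chain.
#' @param constants [scoring_constants()] (provides `covalent_tolerance`).
#' @return A list of class `cqa_molgraph` with `elements` (character),
#'   `edges` (2-column integer matrix, i < j), `coords` (n x 3) and
#'   `atom_names`.
#' @export
build_molecular_graph <- function(ligand, constants = scoring_constants()) {
  stopifnot(ligand$molecule_class == "SMALL_MOLECULE")
  el <- toupper(ligand$atoms$element)
  unknown <- setdiff(unique(el), names(COVALENT_RADII))
  if (length(unknown) > 0L)
    stop("no covalent radius for element(s): ",
         paste(unknown, collapse = ", "), " in ligand ", ligand$chain_id)
  co <- chain_coords(ligand)
  n <- nrow(co)
  edges <- matrix(integer(0), 0, 2)
  if (n > 1L) {
    d <- sqrt(cross_dist2(co, co))
    rad <- COVALENT_RADII[el]
    lim <- outer(rad, rad, "+") + constants$covalent_tolerance
    hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
    edges <- unname(cbind(hit[, 1], hit[, 2]))
  }
  structure(list(elements = el, edges = edges, coords = co,
                 atom_names = ligand$atoms$name),
            class = "cqa_molgraph")
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
  if (nrow(g$edges) > 0L)
    ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

element_colors <- function(..., graphs = list(...)) {
  all_el <- sort(unique(unlist(lapply(graphs, function(g) g$elements))))
  lapply(graphs, function(g) match(g$elements, all_el))
}

#' Enumerate element-preserving graph isomorphisms
#'
#' All bijections model atoms -> reference atoms that preserve both element
#' labels and covalent connectivity (VF2). An empty list means the ligands
#' are not the same molecule. More matches than `constants$match_cap` is an
#' error: the molecule is too symmetric for exhaustive enumeration and a
#' user-supplied mapping is required.
#'
#' @param model_graph,ref_graph Graphs from [build_molecular_graph()].
#' @param constants [scoring_constants()].
#' @return List of integer vectors `m` such that model atom i pairs with
#'   reference atom `m[i]`.
#' @export
enumerate_matches <- function(model_graph, ref_graph,
                              constants = scoring_constants()) {
  if (length(model_graph$elements) == 0L || length(ref_graph$elements) == 0L)
    stop("cannot match empty molecular graphs")
  if (length(model_graph$elements) != length(ref_graph$elements))
    return(list())
  cols <- element_colors(model_graph, ref_graph)
  g1 <- as_igraph(model_graph)
  g2 <- as_igraph(ref_graph)
  n_iso <- igraph::count_isomorphisms(g1, g2, method = "vf2",
                                      vertex.color1 = cols[[1]],
                                      vertex.color2 = cols[[2]])
  if (n_iso > constants$match_cap)
    stop("ligand symmetry produces ", n_iso, " atom mappings (cap ",
         constants$match_cap, "); supply an explicit mapping instead")
  maps <- igraph::isomorphisms(g1, g2, method = "vf2",
                               vertex.color1 = cols[[1]],
                               vertex.color2 = cols[[2]])
  out <- lapply(maps, function(m) {
    m <- as.integer(m)
    # igraph returns the correspondence indexed by the second graph
    # (m[i] = model vertex matching reference vertex i); invert it so that
    # out[[k]][i] is the reference atom paired with model atom i
    inv <- integer(length(m))
    inv[m] <- seq_along(m)
    inv
  })
  for (m in out) {
    if (!identical(model_graph$elements, ref_graph$elements[m]))
      stop("internal error: isomorphism does not preserve element labels")
  }
  out
}

# Reference receptor pocket: residues with any heavy atom within
# `interface_cutoff` of any ligand heavy atom.
pocket_residues <- function(ref_receptor, ref_ligand, constants) {
  md <- residue_pair_mindist(ref_receptor, ref_ligand)
  which(apply(md, 1, min) <= constants$interface_cutoff)
}

#' Pocket-aligned small-molecule LRMSD
#'
#' Superposes the model on the reference over the backbone atoms of the
#' receptor pocket (reference receptor residues with any heavy atom within
#' the 10 Angstrom interface cutoff of the ligand), applies the transform to
#' the model ligand, and reports the minimum all-heavy-atom RMSD over every
#' element- and connectivity-preserving atom mapping between the two
#' ligands. Symmetric molecules are thereby scored on their best equivalent
#' atom assignment.
#'
#' @param model_receptor,ref_receptor The polymer chain the ligand binds,
#'   in model and reference.
#' @param model_ligand,ref_ligand The `SMALL_MOLECULE` chains.
#' @param receptor_corr Residue correspondence model vs reference receptor.
#' @param constants [scoring_constants()].
#' @return List with `lrmsd`, `mapping` (the achieving atom mapping,
#'   model index -> reference index), `n_mappings` and `pocket_size`.
#' @export
pocket_aligned_lrmsd <- function(model_receptor, ref_receptor,
                                 model_ligand, ref_ligand,
                                 receptor_corr,
                                 constants = scoring_constants()) {
  g_m <- build_molecular_graph(model_ligand, constants)
  g_r <- build_molecular_graph(ref_ligand, constants)
  maps <- enumerate_matches(g_m, g_r, constants)
  if (length(maps) == 0L)
    stop("model ligand ", model_ligand$chain_id,
         " is not isomorphic to reference ligand ", ref_ligand$chain_id,
         " (different molecule)")
  pocket <- pocket_residues(ref_receptor, ref_ligand, constants)
  if (length(pocket) == 0L)
    stop("empty pocket: no reference receptor residue within ",
         constants$interface_cutoff, " A of ligand ", ref_ligand$chain_id)
  pb <- paired_backbone_coords(model_receptor, ref_receptor, receptor_corr,
                               pocket,
                               backbone_names(ref_receptor$molecule_class,
                                              constants))
  if (is.null(pb$ref) || nrow(pb$ref) < 3L)
    stop("fewer than 3 paired pocket backbone atoms")
  fit <- superpose(pb$ref, pb$model)
  mod_xyz <- apply_transform(g_m$coords, fit)
  ref_xyz <- g_r$coords
  best <- Inf; best_map <- NULL
  for (mp in maps) {
    r <- paired_rmsd(mod_xyz, ref_xyz[mp, , drop = FALSE])
    if (r < best) { best <- r; best_map <- mp }
  }
  list(lrmsd = best, mapping = best_map, n_mappings = length(maps),
       pocket_size = length(pocket))
}

# Full record for a ligand-polymer interface (only the LRMSD is defined).
score_ligand_interface <- function(model_receptor, model_ligand,
                                   ref_receptor, ref_ligand,
                                   receptor_corr,
                                   constants = scoring_constants()) {
  pl <- pocket_aligned_lrmsd(model_receptor, ref_receptor,
                             model_ligand, ref_ligand,
                             receptor_corr, constants)
  clashes <- count_clashes(model_receptor, model_ligand,
                           constants$clash_cutoff)
  structure(list(
    kind = "small_molecule",
    fnat = NA_real_, fnonnat = NA_real_,
    irmsd = NA_real_, lrmsd = pl$lrmsd,
    dockq = NA_real_, capri_class = NA_character_,
    clashes = clashes,
    native_contacts = NA_integer_, model_contacts = NA_integer_,
    skipped_atoms = 0L,
    n_atom_mappings = pl$n_mappings, pocket_size = pl$pocket_size,
    receptor_chain = ref_receptor$chain_id,
    ligand_chain = ref_ligand$chain_id,
    model_chains = c(model_receptor$chain_id, model_ligand$chain_id),
    ref_chains = c(ref_receptor$chain_id, ref_ligand$chain_id)
  ), class = "cqa_interface")
}
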