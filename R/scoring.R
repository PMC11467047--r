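# Interface scoring for one model/reference chain pair: native contacts,
# interface RMSD, ligand RMSD, clash count and the combined quality score.
#
# All distances are over heavy atoms. The combined score for an interface is
#
#   DockQ = 1/3 * ( fnat + 1/(1 + (iRMSD/a)^2) + 1/(1 + (LRMSD/b)^2) )
#
# with a = 1.5 A and b = 8.5 A, giving a continuous value in [0, 1] from
# incorrect to high quality.

# Backbone atom-name set for a chain's molecule class.
backbone_names <- function(molecule_class, constants) {
  if (molecule_class == "NUCLEIC") constants$nucleic_backbone
  else constants$protein_backbone
}

# Residue-level contact detection: minimum heavy-atom distance per residue
# pair, via one cross-distance matrix aggregated by residue index.
residue_pair_mindist <- function(chain_a, chain_b) {
  d2 <- cross_dist2(chain_coords(chain_a), chain_coords(chain_b))
  ra <- chain_a$atoms$res_idx
  rb <- chain_b$atoms$res_idx
  # min over atoms within each residue pair
  na <- max(ra); nb <- max(rb)
  grp <- (ra[row(d2)] - 1L) * nb + rb[col(d2)]
  mins <- rep(Inf, na * nb)
  agg <- tapply(as.numeric(d2), grp, min)
  mins[as.integer(names(agg))] <- agg
  matrix(sqrt(mins), na, nb, byrow = TRUE)
}

#' Find inter-chain residue contacts
#'
#' Two residues in different chains are in contact when at least one pair of
#' heavy atoms is within `cutoff` of each other (5 Angstrom by default, 4
#' when either chain is a peptide; the caller picks the cutoff).
#'
#' @param chain_a,chain_b Chains of one structure.
#' @param cutoff Distance cutoff in Angstrom.
#' @return `data.frame(res_a, res_b)` of residue indices (a `ContactSet`).
#' @export
find_contacts <- function(chain_a, chain_b, cutoff = 5.0) {
  md <- residue_pair_mindist(chain_a, chain_b)
  idx <- which(md <= cutoff, arr.ind = TRUE)
  data.frame(res_a = idx[, 1], res_b = idx[, 2])
}

# Contact cutoff for a chain pair, peptide-aware.
pair_contact_cutoff <- function(class_a, class_b, constants) {
  if (class_a == "PEPTIDE" || class_b == "PEPTIDE")
    constants$contact_cutoff_peptide
  else constants$contact_cutoff
}

#' Fraction of native contacts
#'
#' `fnat` is the fraction of reference (native) contacts reproduced by the
#' model: a native contact counts as reproduced when the model residues
#' paired to its two reference residues are in contact in the model.
#' `fnonnat` is the fraction of model contacts with no native counterpart;
#' model contacts over unmapped residues are non-native by definition.
#'
#' @param model_contacts,native_contacts Contact sets from [find_contacts()]
#'   (model chain pair and reference chain pair, class-appropriate cutoffs).
#' @param corr_a,corr_b Residue correspondences ([map_residues()]) for the
#'   two chains of the pair, model vs reference.
#' @return List with `fnat`, `fnonnat`, `native_contacts`, `model_contacts`
#'   (counts) and `shared_contacts`.
#' @export
compute_fnat <- function(model_contacts, native_contacts, corr_a, corr_b) {
  if (nrow(native_contacts) == 0L)
    stop("reference chain pair has no native contacts; not an interface")
  # reference residue index -> model residue index
  r2m_a <- stats::setNames(corr_a$pairs$model_idx, corr_a$pairs$ref_idx)
  r2m_b <- stats::setNames(corr_b$pairs$model_idx, corr_b$pairs$ref_idx)
  nat_in_model_a <- r2m_a[as.character(native_contacts$res_a)]
  nat_in_model_b <- r2m_b[as.character(native_contacts$res_b)]
  model_keys <- paste(model_contacts$res_a, model_contacts$res_b)
  nat_keys <- paste(nat_in_model_a, nat_in_model_b)
  mapped <- !is.na(nat_in_model_a) & !is.na(nat_in_model_b)
  shared <- sum(nat_keys[mapped] %in% model_keys)
  fnat <- shared / nrow(native_contacts)
  fnonnat <- if (nrow(model_contacts) == 0L) 0
             else sum(!(model_keys %in% nat_keys[mapped])) / nrow(model_contacts)
  list(fnat = fnat, fnonnat = fnonnat,
       native_contacts = nrow(native_contacts),
       model_contacts = nrow(model_contacts),
       shared_contacts = shared)
}

#' Interface residues of a reference chain pair
#'
#' For protein/nucleic pairs, residues with any two heavy atoms within the
#' 10 Angstrom interface cutoff; when either chain is a peptide, residue
#' pairs whose Cbeta atoms (Calpha for glycine) are within 8 Angstrom.
#'
#' @param ref_chain_a,ref_chain_b Reference chains.
#' @param constants [scoring_constants()].
#' @return List with integer residue index vectors `res_a` and `res_b`.
#' @export
define_interface_residues <- function(ref_chain_a, ref_chain_b,
                                      constants = scoring_constants()) {
  peptide <- ref_chain_a$molecule_class == "PEPTIDE" ||
             ref_chain_b$molecule_class == "PEPTIDE"
  if (peptide) {
    ca <- cb_coords(ref_chain_a)
    cb <- cb_coords(ref_chain_b)
    d2 <- cross_dist2(ca$coords, cb$coords)
    idx <- which(d2 <= constants$interface_cutoff_peptide_cb^2, arr.ind = TRUE)
    list(res_a = sort(unique(ca$res_idx[idx[, 1]])),
         res_b = sort(unique(cb$res_idx[idx[, 2]])))
  } else {
    md <- residue_pair_mindist(ref_chain_a, ref_chain_b)
    idx <- which(md <= constants$interface_cutoff, arr.ind = TRUE)
    list(res_a = sort(unique(idx[, 1])), res_b = sort(unique(idx[, 2])))
  }
}

# Cbeta coordinates per residue (Calpha for glycine / missing Cbeta).
cb_coords <- function(chain) {
  at <- chain$atoms
  pick <- integer(0); res <- integer(0)
  for (ri in seq_len(nrow(chain$residues))) {
    rows <- which(at$res_idx == ri)
    hit <- rows[at$name[rows] == "CB"]
    if (length(hit) == 0L) hit <- rows[at$name[rows] == "CA"]
    if (length(hit) >= 1L) { pick <- c(pick, hit[1]); res <- c(res, ri) }
  }
  list(coords = as.matrix(at[pick, c("x", "y", "z")]), res_idx = res)
}

# Gather paired backbone coordinates for a set of reference residues of one
# chain and their model counterparts. Atom intersection semantics: only
# atoms present (by name) in both paired residues contribute.
paired_backbone_coords <- function(model_chain, ref_chain, corr, ref_res,
                                   bb_names) {
  r2m <- stats::setNames(corr$pairs$model_idx, corr$pairs$ref_idx)
  mref <- character(0)
  ref_xyz <- NULL; mod_xyz <- NULL
  skipped <- 0L
  rat <- ref_chain$atoms; mat_ <- model_chain$atoms
  for (rr in ref_res) {
    mm <- r2m[as.character(rr)]
    if (is.na(mm)) next
    rrows <- which(rat$res_idx == rr & rat$name %in% bb_names)
    mrows <- which(mat_$res_idx == mm & mat_$name %in% bb_names)
    common <- intersect(rat$name[rrows], mat_$name[mrows])
    skipped <- skipped + length(union(rat$name[rrows], mat_$name[mrows])) -
      length(common)
    if (length(common) == 0L) next
    rsel <- rrows[match(common, rat$name[rrows])]
    msel <- mrows[match(common, mat_$name[mrows])]
    ref_xyz <- rbind(ref_xyz, as.matrix(rat[rsel, c("x", "y", "z")]))
    mod_xyz <- rbind(mod_xyz, as.matrix(mat_[msel, c("x", "y", "z")]))
  }
  list(ref = ref_xyz, model = mod_xyz, skipped = skipped)
}

#' Interface RMSD
#'
#' Backbone RMSD of the interface residues (defined on the reference, mapped
#' into the model) after least-squares superposition over those same
#' backbone atoms. Backbone means N, CA, C, O for proteins/peptides and P,
#' OP1, OP2, O2'-O5', C1'-C5' for nucleic acids.
#'
#' @param model_a,model_b Model chains; `ref_a,ref_b` reference chains.
#' @param corr_a,corr_b Correspondences model vs reference per chain.
#' @param constants [scoring_constants()].
#' @return List with `irmsd` and `skipped_atoms`.
#' @export
compute_irmsd <- function(model_a, model_b, ref_a, ref_b, corr_a, corr_b,
                          constants = scoring_constants()) {
  iface <- define_interface_residues(ref_a, ref_b, constants)
  pa <- paired_backbone_coords(model_a, ref_a, corr_a, iface$res_a,
                               backbone_names(ref_a$molecule_class, constants))
  pb <- paired_backbone_coords(model_b, ref_b, corr_b, iface$res_b,
                               backbone_names(ref_b$molecule_class, constants))
  ref_xyz <- rbind(pa$ref, pb$ref)
  mod_xyz <- rbind(pa$model, pb$model)
  if (is.null(ref_xyz) || nrow(ref_xyz) < 3L)
    stop("fewer than 3 paired interface backbone atoms for chains ",
         ref_a$chain_id, "/", ref_b$chain_id)
  skipped <- pa$skipped + pb$skipped
  if (skipped > 0L)
    warning(skipped, " backbone atom(s) missing from one structure were ",
            "skipped in the iRMSD", call. = FALSE)
  fit <- superpose(ref_xyz, mod_xyz)
  list(irmsd = fit$rmsd, skipped_atoms = skipped)
}

#' Ligand RMSD (polymer sense)
#'
#' The receptor is the larger of the two reference chains by residue count
#' (ties go to the first chain of the pair). The model is superposed on the
#' reference over all mapped receptor backbone atoms and the RMSD of the
#' mapped ligand backbone is reported without further fitting.
#'
#' @inheritParams compute_irmsd
#' @return List with `lrmsd`, `receptor_chain`, `ligand_chain`.
#' @export
compute_lrmsd <- function(model_a, model_b, ref_a, ref_b, corr_a, corr_b,
                          constants = scoring_constants()) {
  a_is_receptor <- nrow(ref_a$residues) >= nrow(ref_b$residues)
  if (a_is_receptor) {
    rec <- list(m = model_a, r = ref_a, c = corr_a)
    lig <- list(m = model_b, r = ref_b, c = corr_b)
  } else {
    rec <- list(m = model_b, r = ref_b, c = corr_b)
    lig <- list(m = model_a, r = ref_a, c = corr_a)
  }
  pr <- paired_backbone_coords(rec$m, rec$r, rec$c,
                               seq_len(nrow(rec$r$residues)),
                               backbone_names(rec$r$molecule_class, constants))
  pl <- paired_backbone_coords(lig$m, lig$r, lig$c,
                               seq_len(nrow(lig$r$residues)),
                               backbone_names(lig$r$molecule_class, constants))
  if (is.null(pr$ref) || nrow(pr$ref) < 3L)
    stop("insufficient receptor backbone atoms for superposition")
  if (is.null(pl$ref) || nrow(pl$ref) < 1L)
    stop("insufficient ligand backbone atoms for the LRMSD")
  fit <- superpose(pr$ref, pr$model)
  lig_fitted <- apply_transform(pl$model, fit)
  list(lrmsd = paired_rmsd(pl$ref, lig_fitted),
       receptor_chain = rec$r$chain_id, ligand_chain = lig$r$chain_id)
}

#' Count inter-chain clashes
#'
#' Number of heavy-atom pairs across the two model chains closer than the
#' clash cutoff (2 Angstrom by default, about the shortest covalent bond:
#' non-bonded atoms can never be this close in a physical model).
#'
#' @param model_chain_a,model_chain_b Model chains.
#' @param clash_cutoff Distance in Angstrom.
#' @return Integer count.
#' @export
count_clashes <- function(model_chain_a, model_chain_b, clash_cutoff = 2.0) {
  d2 <- cross_dist2(chain_coords(model_chain_a), chain_coords(model_chain_b))
  sum(d2 < clash_cutoff^2)
}

#' Combined interface quality score
#'
#' `DockQ = (fnat + 1/(1+(iRMSD/a)^2) + 1/(1+(LRMSD/b)^2)) / 3` with
#' a = 1.5 and b = 8.5 Angstrom.
#'
#' @param fnat Fraction of native contacts in \[0, 1\].
#' @param irmsd,lrmsd RMSDs in Angstrom (non-negative).
#' @param constants [scoring_constants()].
#' @return Score in \[0, 1\].
#' @export
#' @examples
#' compute_dockq(1, 0, 0)          # 1
#' compute_dockq(0.5, 1.5, 8.5)    # 0.5: every term equals 0.5
compute_dockq <- function(fnat, irmsd, lrmsd,
                          constants = scoring_constants()) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0, lrmsd >= 0)
  (fnat +
     1 / (1 + (irmsd / constants$a)^2) +
     1 / (1 + (lrmsd / constants$b)^2)) / 3
}

#' CAPRI quality class of a score
#'
#' Half-open boundaries from the original calibration of the score:
#' Incorrect < 0.23 <= Acceptable < 0.49 <= Medium < 0.80 <= High.
#'
#' @param dockq Score in \[0, 1\].
#' @param constants [scoring_constants()].
#' @return One of `"Incorrect"`, `"Acceptable"`, `"Medium"`, `"High"`.
#' @export
classify_capri <- function(dockq, constants = scoring_constants()) {
  th <- constants$capri_thresholds
  ifelse(dockq < th[["Acceptable"]], "Incorrect",
  ifelse(dockq < th[["Medium"]], "Acceptable",
  ifelse(dockq < th[["High"]], "Medium", "High")))
}

#' Score one polymer-polymer interface
#'
#' Orchestrates contact detection, fnat, iRMSD, LRMSD, clash counting and
#' the combined score for a mapped model/reference chain pair. The
#' reference pair must have at least one native contact (otherwise it is
#' not an interface and scoring it is an error).
#'
#' @inheritParams compute_irmsd
#' @return A list of class `cqa_interface` with fields `fnat`, `fnonnat`,
#'   `irmsd`, `lrmsd`, `dockq`, `capri_class`, `clashes`,
#'   `native_contacts`, `model_contacts`, `receptor_chain`, `ligand_chain`,
#'   `model_chains`, `ref_chains`.
#' @export
score_interface <- function(model_a, model_b, ref_a, ref_b, corr_a, corr_b,
                            constants = scoring_constants()) {
  cutoff <- pair_contact_cutoff(ref_a$molecule_class, ref_b$molecule_class,
                                constants)
  native <- find_contacts(ref_a, ref_b, cutoff)
  if (nrow(native) == 0L)
    stop("reference chains ", ref_a$chain_id, "/", ref_b$chain_id,
         " share no contacts; not an interface")
  model <- find_contacts(model_a, model_b, cutoff)
  fn <- compute_fnat(model, native, corr_a, corr_b)
  ir <- compute_irmsd(model_a, model_b, ref_a, ref_b, corr_a, corr_b,
                      constants)
  lr <- compute_lrmsd(model_a, model_b, ref_a, ref_b, corr_a, corr_b,
                      constants)
  clashes <- count_clashes(model_a, model_b, constants$clash_cutoff)
  dq <- compute_dockq(fn$fnat, ir$irmsd, lr$lrmsd, constants)
  structure(list(
    kind = "polymer",
    fnat = fn$fnat, fnonnat = fn$fnonnat,
    irmsd = ir$irmsd, lrmsd = lr$lrmsd,
    dockq = dq, capri_class = classify_capri(dq, constants),
    clashes = clashes,
    native_contacts = fn$native_contacts,
    model_contacts = fn$model_contacts,
    skipped_atoms = ir$skipped_atoms,
    receptor_chain = lr$receptor_chain, ligand_chain = lr$ligand_chain,
    model_chains = c(model_a$chain_id, model_b$chain_id),
    ref_chains = c(ref_a$chain_id, ref_b$chain_id)
  ), class = "cqa_interface")
}
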