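# Chain-mapping search: find the assignment of model chains to reference
# chains that maximizes GlobalDockQ, by exhaustive enumeration of the
# injections within each group of equivalent subunits.
#
# Interface scores are mapping-independent for a fixed (model pair,
# reference pair), so they are computed at most once and memoized; the
# candidate scan then only combines cached numbers, which keeps the search
# exhaustive yet cheap. Cache filling may be parallelized; results are
# identical for any worker count.

# All permutations of a vector, in lexicographic order of positions.
all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(v[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
  }
  out
}

# All injective assignments of `from` ids into `to` ids, as named vectors
# (names = from, values = to). When |from| > |to| a maximal subset of `from`
# is used; unassigned ids are absent from the vector.
injections <- function(from, to) {
  nf <- length(from); nt <- length(to)
  if (nf == 0L || nt == 0L) return(list(stats::setNames(character(0), character(0))))
  if (nf <= nt) {
    subsets <- utils::combn(to, nf, simplify = FALSE)
    out <- list()
    for (s in subsets)
      for (p in all_permutations(s))
        out[[length(out) + 1L]] <- stats::setNames(p, from)
    out
  } else {
    subsets <- utils::combn(from, nt, simplify = FALSE)
    out <- list()
    for (s in subsets)
      for (p in all_permutations(to))
        out[[length(out) + 1L]] <- stats::setNames(p, s)
    out
  }
}

n_injections <- function(nf, nt) {
  mx <- max(nf, nt); mn <- min(nf, nt)
  round(factorial(mx) / factorial(mx - mn))
}

# Pair up model and reference equivalence groups by representative:
# identical component code for small molecules, sequence identity at the
# grouping threshold for polymers. Model groups without a reference partner
# are dropped (those chains stay unmapped); reference groups without a
# model partner keep their chains unmapped.
match_groups <- function(model_groups, ref_groups,
                         constants = scoring_constants()) {
  used <- rep(FALSE, length(model_groups))
  matched <- list()
  for (rg in ref_groups) {
    hit <- NA_integer_
    for (k in seq_along(model_groups)) {
      if (used[k]) next
      mg <- model_groups[[k]]
      if ((mg$molecule_class == "SMALL_MOLECULE") !=
          (rg$molecule_class == "SMALL_MOLECULE")) next
      ok <- if (rg$molecule_class == "SMALL_MOLECULE") {
        mg$representative == rg$representative
      } else {
        fam <- function(g) if (g$molecule_class == "NUCLEIC") "nuc" else "aa"
        fam(mg) == fam(rg) &&
          align_sequences(mg$representative, rg$representative)$identity >=
            constants$identity_threshold
      }
      if (ok) { hit <- k; break }
    }
    if (!is.na(hit)) used[hit] <- TRUE
    matched[[length(matched) + 1L]] <- list(
      model_members = if (is.na(hit)) character(0)
                      else model_groups[[hit]]$member_chain_ids,
      ref_members = rg$member_chain_ids)
  }
  matched
}

#' Number of candidate chain mappings
#'
#' Product over matched equivalence groups of the number of injective
#' assignments of model chains to reference chains; a homomer of k
#' identical subunits mapped one-to-one contributes k!.
#'
#' @param model_groups,ref_groups Output of [group_equivalent_chains()] on
#'   the model and reference structures.
#' @param constants [scoring_constants()].
#' @return Integer-valued count (as numeric, since 8! and beyond grow fast).
#' @export
count_mappings <- function(model_groups, ref_groups,
                           constants = scoring_constants()) {
  matched <- match_groups(model_groups, ref_groups, constants)
  sizes <- vapply(matched, function(m) {
    if (length(m$model_members) == 0L) 1
    else n_injections(length(m$model_members), length(m$ref_members))
  }, numeric(1))
  prod(sizes)
}

#' Enumerate candidate chain mappings
#'
#' Yields every assignment of model chains to reference chains compatible
#' with the equivalence groups, each exactly once, in deterministic order.
#'
#' @inheritParams count_mappings
#' @param fixed Optional named character vector of pre-assigned chains
#'   (model id -> reference id); those chains are removed from the free
#'   search and re-attached to every candidate.
#' @return List of named character vectors (model id -> reference id).
#' @export
enumerate_mappings <- function(model_groups, ref_groups, fixed = NULL,
                               constants = scoring_constants()) {
  matched <- match_groups(model_groups, ref_groups, constants)
  if (!is.null(fixed) && length(fixed) > 0L) {
    for (i in seq_along(fixed)) {
      m_id <- names(fixed)[i]; r_id <- unname(fixed[i])
      hit <- FALSE
      for (k in seq_along(matched)) {
        in_m <- m_id %in% matched[[k]]$model_members
        in_r <- r_id %in% matched[[k]]$ref_members
        if (in_m && in_r) {
          matched[[k]]$model_members <-
            setdiff(matched[[k]]$model_members, m_id)
          matched[[k]]$ref_members <- setdiff(matched[[k]]$ref_members, r_id)
          hit <- TRUE; break
        } else if (in_m || in_r) {
          stop("fixed assignment ", m_id, ":", r_id,
               " crosses equivalence groups (chains are not the same subunit)")
        }
      }
      if (!hit)
        stop("fixed assignment ", m_id, ":", r_id,
             " does not match any equivalence group")
    }
  }
  per_group <- lapply(matched, function(m) {
    if (length(m$model_members) == 0L)
      list(stats::setNames(character(0), character(0)))
    else injections(m$model_members, m$ref_members)
  })
  combos <- list(stats::setNames(character(0), character(0)))
  for (g in per_group) {
    combos <- unlist(lapply(combos, function(base) {
      lapply(g, function(asgn) c(base, asgn))
    }), recursive = FALSE)
  }
  lapply(combos, function(m) c(fixed, m))
}

# --- reference interfaces and the score cache --------------------------------

# All reference chain pairs with at least one native contact, in chain
# order. Ligand-ligand pairs are skipped (no defined measure).
reference_interfaces <- function(ref, constants = scoring_constants()) {
  ids <- chain_ids(ref)
  out <- list()
  if (length(ids) < 2L) return(out)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      ca <- ref$chains[[ids[i]]]; cb <- ref$chains[[ids[j]]]
      lig_a <- ca$molecule_class == "SMALL_MOLECULE"
      lig_b <- cb$molecule_class == "SMALL_MOLECULE"
      if (lig_a && lig_b) next
      cutoff <- if (lig_a || lig_b) constants$contact_cutoff
                else pair_contact_cutoff(ca$molecule_class,
                                         cb$molecule_class, constants)
      if (nrow(find_contacts(ca, cb, cutoff)) > 0L)
        out[[length(out) + 1L]] <- list(
          ref_a = ids[i], ref_b = ids[j],
          kind = if (lig_a || lig_b) "small_molecule" else "polymer",
          # put the polymer first for ligand interfaces
          receptor_first = !lig_a)
    }
  }
  out
}

# Memoized correspondence between one model chain and one reference chain.
corr_cache_get <- function(cache, model, ref, m_id, r_id, mode) {
  key <- paste0("corr\r", m_id, "\r", r_id)
  if (is.null(cache[[key]]))
    cache[[key]] <- map_residues(model$chains[[m_id]], ref$chains[[r_id]],
                                 mode = mode)
  cache[[key]]
}

# Memoized interface score for (model pair assigned to reference pair).
# Returns a cqa_interface. Key is mapping-independent.
pair_score_get <- function(cache, model, ref, iface, m_a, m_b, mode,
                           constants) {
  key <- paste0("iface\r", iface$ref_a, "\r", iface$ref_b, "\r", m_a, "\r", m_b)
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- compute_pair_score(model, ref, iface, m_a, m_b, mode, constants,
                            cache)
  cache[[key]] <- res
  res
}

compute_pair_score <- function(model, ref, iface, m_a, m_b, mode, constants,
                               cache) {
  if (iface$kind == "polymer") {
    corr_a <- corr_cache_get(cache, model, ref, m_a, iface$ref_a, mode)
    corr_b <- corr_cache_get(cache, model, ref, m_b, iface$ref_b, mode)
    score_interface(model$chains[[m_a]], model$chains[[m_b]],
                    ref$chains[[iface$ref_a]], ref$chains[[iface$ref_b]],
                    corr_a, corr_b, constants)
  } else {
    # orient: receptor (polymer) first
    if (iface$receptor_first) {
      r_rec <- iface$ref_a; r_lig <- iface$ref_b
      m_rec <- m_a; m_lig <- m_b
    } else {
      r_rec <- iface$ref_b; r_lig <- iface$ref_a
      m_rec <- m_b; m_lig <- m_a
    }
    corr <- corr_cache_get(cache, model, ref, m_rec, r_rec, mode)
    score_ligand_interface(model$chains[[m_rec]], model$chains[[m_lig]],
                           ref$chains[[r_rec]], ref$chains[[r_lig]],
                           corr, constants)
  }
}

# Objective contribution of one interface record. Polymer interfaces
# contribute their DockQ. Small-molecule interfaces have no DockQ; they
# enter the search objective through the LRMSD-derived surrogate
# 1/(1 + (LRMSD/b)^2) so equivalent ligand copies are assigned optimally,
# but they are excluded from the reported GlobalDockQ mean.
iface_objective <- function(rec, constants) {
  if (rec$kind == "polymer") rec$dockq
  else 1 / (1 + (rec$lrmsd / constants$b)^2)
}

#' GlobalDockQ of one chain mapping
#'
#' Scores every reference interface under the given mapping and averages
#' the DockQ values over all reference polymer interfaces; a reference
#' interface with an unmapped chain contributes 0 (missing chains are
#' penalized). Small-molecule interfaces are reported with their
#' pocket-aligned LRMSD only and are excluded from the GlobalDockQ mean.
#'
#' @param model,ref Parsed structures.
#' @param mapping Named character vector, model chain id -> reference chain
#'   id (partial mappings allowed).
#' @param cache Environment used for memoization (optional; one is created
#'   if missing).
#' @param mode Residue mapping mode, `"ALIGNMENT"` or `"NUMBERING"`.
#' @param constants [scoring_constants()].
#' @return A list of class `cqa_global` with `mapping`, `global_dockq`,
#'   `per_interface` (named list of interface records; unmapped interfaces
#'   appear as `NULL` entries scored 0) and `n_evaluated`.
#' @export
global_dockq <- function(model, ref, mapping, cache = new.env(parent = emptyenv()),
                         mode = "ALIGNMENT", constants = scoring_constants()) {
  ifaces <- reference_interfaces(ref, constants)
  if (length(ifaces) == 0L)
    stop("reference structure has no interfaces (no chain pair in contact)")
  inv <- stats::setNames(names(mapping), unname(mapping))  # ref -> model
  per <- list()
  poly_scores <- numeric(0)
  for (ifc in ifaces) {
    key <- paste0(ifc$ref_a, ":", ifc$ref_b)
    m_a <- inv[ifc$ref_a]; m_b <- inv[ifc$ref_b]
    if (is.na(m_a) || is.na(m_b)) {
      per[[key]] <- list(kind = ifc$kind, unmapped = TRUE,
                         ref_chains = c(ifc$ref_a, ifc$ref_b))
      if (ifc$kind == "polymer") poly_scores <- c(poly_scores, 0)
      next
    }
    rec <- pair_score_get(cache, model, ref, ifc, m_a, m_b, mode, constants)
    per[[key]] <- rec
    if (ifc$kind == "polymer") poly_scores <- c(poly_scores, rec$dockq)
  }
  gd <- if (length(poly_scores) > 0L) mean(poly_scores) else NA_real_
  structure(list(mapping = mapping, global_dockq = gd,
                 per_interface = per, n_evaluated = 1L),
            class = "cqa_global")
}

#' Search for the optimal chain mapping
#'
#' Exhaustively enumerates all chain mappings compatible with the
#' equivalence groups (and any user constraints) and returns the one
#' maximizing GlobalDockQ. Scores are memoized per (model pair, reference
#' pair), so each interface is computed at most once regardless of how many
#' mappings share it; the candidate scan then only combines cached values.
#' Results are identical for any `n_workers`.
#'
#' @param model,ref Parsed structures.
#' @param constraints Optional list with `fixed` (named character vector,
#'   model id -> reference id) and/or `ref_subset` (reference chain ids to
#'   restrict scoring to), as produced by [parse_mapping_spec()].
#' @param n_workers Number of worker processes for cache filling (default
#'   8, capped at the number of distinct interface computations). Forked
#'   workers are used where available; the result does not depend on this.
#' @param mode Residue mapping mode, `"ALIGNMENT"` or `"NUMBERING"`.
#' @param constants [scoring_constants()].
#' @return A `cqa_global` (see [global_dockq()]) with `n_evaluated` set to
#'   the number of candidate mappings scanned.
#' @export
find_optimal_mapping <- function(model, ref, constraints = NULL,
                                 n_workers = 8L, mode = "ALIGNMENT",
                                 constants = scoring_constants()) {
  if (!is.null(constraints$ref_subset)) {
    keep <- chain_ids(ref) %in% constraints$ref_subset
    if (!any(keep)) stop("reference subset matches no chains")
    ref <- new_structure(ref$chains[keep], ref$source_path, ref$format)
  }
  model_groups <- group_equivalent_chains(model, constants$identity_threshold)
  ref_groups <- group_equivalent_chains(ref, constants$identity_threshold)
  fixed <- constraints$fixed
  if (!is.null(fixed)) {
    bad_m <- setdiff(names(fixed), chain_ids(model))
    bad_r <- setdiff(unname(fixed), chain_ids(ref))
    if (length(bad_m) || length(bad_r))
      stop("mapping constraint names unknown chain(s): ",
           paste(c(bad_m, bad_r), collapse = ", "))
  }
  candidates <- enumerate_mappings(model_groups, ref_groups, fixed = fixed,
                                   constants = constants)
  if (length(candidates) == 0L) stop("no candidate chain mappings")

  ifaces <- reference_interfaces(ref, constants)
  if (length(ifaces) == 0L)
    stop("reference structure has no interfaces (no chain pair in contact)")

  cache <- new.env(parent = emptyenv())
  fill_score_cache(cache, model, ref, ifaces, candidates, n_workers, mode,
                   constants)

  best <- NULL; best_obj <- -Inf
  for (cand in candidates) {
    inv <- stats::setNames(names(cand), unname(cand))
    obj <- 0
    for (ifc in ifaces) {
      m_a <- inv[ifc$ref_a]; m_b <- inv[ifc$ref_b]
      if (is.na(m_a) || is.na(m_b)) next
      rec <- pair_score_get(cache, model, ref, ifc, m_a, m_b, mode, constants)
      obj <- obj + iface_objective(rec, constants)
    }
    obj <- obj / length(ifaces)
    if (obj > best_obj + 1e-12) { best_obj <- obj; best <- cand }
  }
  res <- global_dockq(model, ref, best, cache = cache, mode = mode,
                      constants = constants)
  res$n_evaluated <- length(candidates)
  res
}

# Precompute every interface score that any candidate mapping can need:
# for each reference interface, every (model chain for ref_a, model chain
# for ref_b) combination occurring in the candidates. Parallel workers
# each return a named list merged into the cache; single-worker fallback
# gives bit-identical results.
fill_score_cache <- function(cache, model, ref, ifaces, candidates,
                             n_workers, mode, constants) {
  tasks <- list()
  seen <- new.env(parent = emptyenv())
  for (ifc in ifaces) {
    for (cand in candidates) {
      inv <- stats::setNames(names(cand), unname(cand))
      m_a <- inv[ifc$ref_a]; m_b <- inv[ifc$ref_b]
      if (is.na(m_a) || is.na(m_b)) next
      key <- paste0("iface\r", ifc$ref_a, "\r", ifc$ref_b, "\r", m_a, "\r", m_b)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        tasks[[length(tasks) + 1L]] <- list(key = key, iface = ifc,
                                            m_a = unname(m_a), m_b = unname(m_b))
      }
    }
  }
  if (length(tasks) == 0L) return(invisible(cache))
  n_workers <- max(1L, min(as.integer(n_workers), length(tasks)))
  run_one <- function(tk) {
    compute_pair_score(model, ref, tk$iface, tk$m_a, tk$m_b, mode, constants,
                       new.env(parent = emptyenv()))
  }
  results <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(tasks, run_one, mc.cores = n_workers)
  } else {
    lapply(tasks, run_one)
  }
  for (i in seq_along(tasks)) {
    r <- results[[i]]
    if (inherits(r, "try-error") || inherits(r, "condition")) {
      # recompute serially so the error surfaces with context
      r <- run_one(tasks[[i]])
    }
    cache[[tasks[[i]]$key]] <- r
  }
  # correspondences were computed inside workers; warm the shared cache too
  invisible(cache)
}
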