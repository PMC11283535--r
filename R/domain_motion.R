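# Interdomain-motion pipeline: canonicalise a reference structure onto the
# principal axes of its cap domain, express every structure's cap-aligned ->
# core-aligned rotation in that frame, and report pitch/roll/yaw, hinge
# angle, non-H RMSD and a conformer class.

#' Canonicalise a reference structure onto its cap principal axes
#'
#' Translates the model so the centroid of its cap C-alpha atoms sits at the
#' origin and rotates it so the cap principal axes coincide with the
#' coordinate axes (largest variance along x = roll axis, second along y =
#' pitch axis, third along z = yaw axis). Axis signs are fixed by positive
#' projection onto the core-to-cap centroid vector; the basis is forced
#' right-handed. This sets the coordinate basis in which intrinsic Euler
#' angles are computed, so the operation is idempotent.
#'
#' @param reference A [structure_model()].
#' @param domains A [domain_definition()].
#' @param chain Chain identifier (default: first chain).
#' @return The canonicalised [structure_model()].
#' @export
canonicalize_reference <- function(reference, domains = domain_definition(),
                                   chain = NULL) {
  cap <- select_domain_coords(reference, domains, "cap", "ca_only", chain)
  core <- select_domain_coords(reference, domains, "core", "ca_only", chain)
  orient <- colMeans(cap$xyz) - colMeans(core$xyz)
  pa <- principal_axes(cap$xyz, orient = orient)
  # coordinates re-expressed in the cap-axes frame: x' = t(A) (x - centroid)
  tr <- rigid_transform(t(pa$axes), as.numeric(-t(pa$axes) %*% pa$centroid))
  transform_structure(reference, tr)
}

#' Rotation between the cap-aligned and core-aligned poses of a structure
#'
#' The structure is first superposed onto the canonical reference using
#' shared cap C-alpha atoms, then using shared core C-alpha atoms. The
#' returned transform takes the cap-aligned pose to the core-aligned pose,
#' expressed in the canonical (cap principal axes) frame; its rotation is the
#' interdomain rotation whose Euler decomposition gives pitch/roll/yaw.
#'
#' @param structure A [structure_model()].
#' @param canonical_reference The reference after [canonicalize_reference()].
#' @param domains A [domain_definition()].
#' @param chain_s,chain_r Chain of the structure / reference.
#' @return A [rigid_transform()].
#' @export
interdomain_transform <- function(structure, canonical_reference,
                                  domains = domain_definition(),
                                  chain_s = NULL, chain_r = NULL) {
  cap_res <- ranges_to_residues(domains$cap_ranges)
  core_res <- ranges_to_residues(domains$core_ranges)
  pair_cap <- pair_shared_atoms(structure, canonical_reference, "ca_only",
                                chain_s, chain_r, residues = cap_res)
  pair_core <- pair_shared_atoms(structure, canonical_reference, "ca_only",
                                 chain_s, chain_r, residues = core_res)
  fit_cap <- kabsch_superpose(pair_cap$xyz_a, pair_cap$xyz_b)$transform
  fit_core <- kabsch_superpose(pair_core$xyz_a, pair_core$xyz_b)$transform
  R <- fit_core$rotation %*% t(fit_cap$rotation)
  translation <- fit_core$translation -
    as.numeric(R %*% fit_cap$translation)
  rigid_transform(R, translation)
}

#' Full motion profile of one structure against the canonical reference
#'
#' Combines the interdomain rotation (Euler angles via
#' [euler_from_rotation()], hinge angle via [rotation_angle()]) with the
#' all-shared-atom non-hydrogen RMSD to the reference after superposition,
#' and optionally a conformer class from labelled centroids.
#'
#' @inheritParams interdomain_transform
#' @param centroids Optional centroid table for [classify_conformer()].
#' @param convention Euler convention tag (see [euler_from_rotation()]).
#' @param cutoff Classification distance cutoff in degrees.
#' @return A one-row `data.frame` (class `motion_result`) with columns
#'   `structure_id`, `chain`, `pitch`, `roll`, `yaw` (degrees),
#'   `hinge_angle` (degrees), `rmsd_to_reference_nonH` (Angstrom),
#'   `n_shared_nonH` and `conformer_class`.
#' @export
motion_profile <- function(structure, canonical_reference,
                           domains = domain_definition(),
                           chain_s = NULL, chain_r = NULL,
                           centroids = NULL, convention = "xyz",
                           cutoff = 8) {
  tr <- interdomain_transform(structure, canonical_reference, domains,
                              chain_s, chain_r)
  eu <- euler_from_rotation(tr$rotation, convention)
  hinge <- rotation_angle(tr$rotation)
  pair_all <- pair_shared_atoms(structure, canonical_reference, "non_h",
                                chain_s, chain_r)
  fit_all <- kabsch_superpose(pair_all$xyz_a, pair_all$xyz_b)
  res <- data.frame(structure_id = structure$identifier,
                    chain = if (is.null(chain_s)) structure$atoms$chain_id[1] else chain_s,
                    pitch = eu$pitch, roll = eu$roll, yaw = eu$yaw,
                    hinge_angle = hinge,
                    rmsd_to_reference_nonH = fit_all$rmsd,
                    n_shared_nonH = fit_all$n_atoms,
                    conformer_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(centroids)) {
    res$conformer_class <- classify_conformer(res, centroids, cutoff)$label
  }
  class(res) <- c("motion_result", class(res))
  res
}

#' Classify a conformer from its Euler angles
#'
#' Nearest labelled centroid in (pitch, roll, yaw) Euclidean space
#' (degrees); `"unassigned"` when the nearest distance exceeds `cutoff`.
#' Ties are broken deterministically by centroid row order (and logged).
#'
#' @param result A `motion_result` row, or a list with `pitch`, `roll`, `yaw`.
#' @param centroids Data frame with columns `label`, `pitch`, `roll`, `yaw`.
#' @param cutoff Distance cutoff in degrees (default 8).
#' @return List with `label`, `distance` (degrees) and `nearest` (ranked
#'   centroid table).
#' @export
classify_conformer <- function(result, centroids, cutoff = 8) {
  if (is.null(centroids) || nrow(centroids) == 0L) {
    stop("empty centroid set", call. = FALSE)
  }
  stopifnot(all(c("label", "pitch", "roll", "yaw") %in% names(centroids)))
  p <- c(result$pitch, result$roll, result$yaw)
  d <- sqrt((centroids$pitch - p[1])^2 + (centroids$roll - p[2])^2 +
              (centroids$yaw - p[3])^2)
  ord <- order(d)  # stable: ties keep centroid row order
  if (sum(abs(d - min(d)) < 1e-12) > 1L) {
    message("conformer tie at distance ", format(min(d)),
            "; broken by centroid order (", centroids$label[ord[1]], ")")
  }
  label <- if (d[ord[1]] > cutoff) "unassigned" else as.character(centroids$label[ord[1]])
  list(label = label, distance = d[ord[1]],
       nearest = data.frame(label = centroids$label[ord], distance = d[ord]))
}

#' Batch interdomain-motion landscape
#'
#' Runs [motion_profile()] for every (structure, chain) combination against a
#' shared reference, returning one row each in deterministic order.
#' Per-structure failures are recorded in an `error` column rather than
#' aborting the batch; duplicated structure identifiers are suffixed.
#'
#' @param structures List of [structure_model()] objects (or paths to PDB
#'   files, read on the fly).
#' @param reference Reference [structure_model()] (canonicalised internally).
#' @param domains A [domain_definition()].
#' @param centroids Optional centroid table for classification.
#' @param chains Optional character vector of chains to evaluate per
#'   structure (default: every chain present).
#' @param out Optional path; when given the table is written as
#'   tab-separated text with a header.
#' @param convention Euler convention tag.
#' @return A `data.frame` of motion results (one row per structure/chain).
#' @export
batch_landscape <- function(structures, reference,
                            domains = domain_definition(), centroids = NULL,
                            chains = NULL, out = NULL, convention = "xyz") {
  template <- data.frame(structure_id = character(), chain = character(),
                         pitch = numeric(), roll = numeric(), yaw = numeric(),
                         hinge_angle = numeric(),
                         rmsd_to_reference_nonH = numeric(),
                         n_shared_nonH = integer(),
                         conformer_class = character(), error = character(),
                         stringsAsFactors = FALSE)
  if (is.character(reference)) reference <- read_structure(reference)
  canon <- canonicalize_reference(reference, domains)
  rows <- list()
  ids_seen <- character()
  for (s in structures) {
    if (is.character(s)) s <- read_structure(s)
    id <- s$identifier
    if (id %in% ids_seen) {
      new_id <- make.unique(c(ids_seen, id))[length(ids_seen) + 1L]
      warning("duplicate structure id '", id, "' renamed to '", new_id, "'")
      s$identifier <- id <- new_id
    }
    ids_seen <- c(ids_seen, id)
    ch <- if (is.null(chains)) unique(s$atoms$chain_id) else chains
    for (one_chain in ch) {
      row <- tryCatch({
        r <- motion_profile(s, canon, domains, chain_s = one_chain,
                            centroids = centroids, convention = convention)
        r$error <- NA_character_
        as.data.frame(r)
      }, error = function(e) {
        data.frame(structure_id = id, chain = one_chain,
                   pitch = NA_real_, roll = NA_real_, yaw = NA_real_,
                   hinge_angle = NA_real_, rmsd_to_reference_nonH = NA_real_,
                   n_shared_nonH = NA_integer_,
                   conformer_class = NA_character_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else template
  rownames(tab) <- NULL
  if (!is.null(out)) {
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Build conformer centroids from a motion-result table
#'
#' Averages pitch/roll/yaw per class label of an annotated motion-result
#' table (e.g. reference structures of known conformation), yielding a
#' centroid table for [classify_conformer()].
#'
#' @param results A motion-result `data.frame` with a `label` column.
#' @return Data frame with columns `label`, `pitch`, `roll`, `yaw`.
#' @export
conformer_centroids <- function(results) {
  stopifnot(all(c("label", "pitch", "roll", "yaw") %in% names(results)))
  agg <- aggregate(results[, c("pitch", "roll", "yaw")],
                   by = list(label = results$label), FUN = mean)
  agg[order(agg$label), , drop = FALSE]
}
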