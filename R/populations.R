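# Species populations from per-residue peak intensities, and two-state
# dissociation-constant estimation from populations.

#' Construct an intensity table
#'
#' Per-residue peak intensities for two or more coexisting species, as a
#' data frame with a `residue_number` column followed by one non-negative
#' intensity column per species.
#'
#' @param df Data frame as described.
#' @return The validated data frame (class `intensity_table`).
#' @export
intensity_table <- function(df) {
  if (!"residue_number" %in% names(df)) {
    stop("intensity table needs a residue_number column", call. = FALSE)
  }
  species <- setdiff(names(df), "residue_number")
  if (length(species) < 2L) stop("need at least 2 species columns", call. = FALSE)
  vals <- as.matrix(df[, species, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("intensities must be non-negative", call. = FALSE)
  if (anyDuplicated(df$residue_number)) {
    stop("duplicate residue numbers in intensity table", call. = FALSE)
  }
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("intensity_table", "data.frame"))
}

#' Read an intensity table from CSV
#'
#' @param path CSV with a `residue_number` column and one intensity column
#'   per species.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path) {
  intensity_table(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' Fractional populations of coexisting species from peak intensities
#'
#' For every residue where all species have finite intensities and a nonzero
#' total, the per-residue fraction of species s is `I_s / sum(I)`; the
#' population of each species is the mean of these fractions over qualifying
#' residues (so populations sum to one exactly), with the between-residue
#' standard deviation as the dispersion.
#'
#' @param table An [intensity_table()].
#' @param min_residues Minimum number of complete residue rows (default 20).
#' @return A `species_populations` object: list with `fractions` (named),
#'   `sd` (named), `n_residues` and `per_residue` fraction matrix.
#' @export
estimate_populations <- function(table, min_residues = 20L) {
  stopifnot(inherits(table, "intensity_table"))
  species <- setdiff(names(table), "residue_number")
  vals <- as.matrix(table[, species, drop = FALSE])
  total <- rowSums(vals)
  complete <- apply(is.finite(vals), 1, all) & is.finite(total) & total > 0
  if (sum(complete) < min_residues) {
    stop("only ", sum(complete), " complete residue rows; need at least ",
         min_residues, call. = FALSE)
  }
  frac <- vals[complete, , drop = FALSE] / total[complete]
  fractions <- colMeans(frac)
  structure(list(fractions = fractions,
                 sd = apply(frac, 2, sd),
                 n_residues = sum(complete),
                 per_residue = frac),
            class = "species_populations")
}

#' @export
print.species_populations <- function(x, ...) {
  cat(sprintf("Populations over %d residues:\n", x$n_residues))
  for (s in names(x$fractions)) {
    cat(sprintf("  %-20s %5.1f%% (SD %.1f%%)\n", s, 100 * x$fractions[s],
                100 * x$sd[s]))
  }
  invisible(x)
}

#' Two-state dissociation constant from bound/free populations
#'
#' Under the excess-ligand approximation (free ligand ~ total),
#' `Kd = L_total * p_free / p_bound`. When the total protein concentration
#' is supplied the exact free-ligand correction
#' `L_free = L_total - p_bound * P_total` is applied instead.
#'
#' @param populations A `species_populations` with exactly two species, or a
#'   named numeric vector of two fractions.
#' @param ligand_total Total ligand concentration, mM.
#' @param bound_label,free_label Names of the bound / free species (defaults:
#'   first and second species).
#' @param protein_total Optional total protein concentration, mM, enabling
#'   the free-ligand depletion correction.
#' @return A `kd_estimate`: list with `kd` (mM), `kd_1sf` (rounded to 1
#'   significant figure for summary display), `ligand_total`, `p_bound`,
#'   `p_free` and `approximation` (`"excess_ligand"` or `"depletion_corrected"`).
#' @export
estimate_kd <- function(populations, ligand_total, bound_label = NULL,
                        free_label = NULL, protein_total = NULL) {
  fr <- if (inherits(populations, "species_populations")) populations$fractions
        else populations
  if (is.null(names(fr))) names(fr) <- c("bound", "free")[seq_along(fr)]
  if (is.null(bound_label)) bound_label <- names(fr)[1]
  if (is.null(free_label)) free_label <- names(fr)[2]
  if (!all(c(bound_label, free_label) %in% names(fr))) {
    stop("bound/free labels not found among species", call. = FALSE)
  }
  p_bound <- unname(fr[bound_label])
  p_free <- unname(fr[free_label])
  tot <- p_bound + p_free
  if (abs(tot - 1) > 1e-9) {  # renormalise over the two states considered
    p_bound <- p_bound / tot
    p_free <- p_free / tot
  }
  if (ligand_total <= 0) stop("ligand_total must be positive", call. = FALSE)
  if (p_bound <= 0) stop("no bound population", call. = FALSE)
  l_free <- if (is.null(protein_total)) ligand_total
            else max(ligand_total - p_bound * protein_total, 0)
  kd <- l_free * p_free / p_bound
  structure(list(kd = kd,
                 kd_1sf = signif(kd, 1),
                 ligand_total = ligand_total,
                 p_bound = p_bound, p_free = p_free,
                 approximation = if (is.null(protein_total)) "excess_ligand"
                                 else "depletion_corrected"),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd = %.3f mM (~%g mM) at %g mM total ligand (bound %.1f%%, free %.1f%%; %s)\n",
              x$kd, x$kd_1sf, x$ligand_total, 100 * x$p_bound, 100 * x$p_free,
              x$approximation))
  invisible(x)
}

#' Bound fraction of the two-state binding isotherm
#'
#' `p_bound = L / (L + Kd)` under the excess-ligand approximation; useful
#' for round-trip checks of [estimate_kd()].
#'
#' @param kd Dissociation constant, mM.
#' @param ligand Free (~total) ligand concentration, mM.
#' @return Bound fraction.
#' @export
binding_isotherm <- function(kd, ligand) {
  stopifnot(kd > 0, ligand >= 0)
  ligand / (ligand + kd)
}
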