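# Structure I/O: reading/writing PDB (and mmCIF) files into a light
# data-frame atom model, residue-range domain definitions, atom selection
# and shared-atom pairing between models.

#' Construct a structure model
#'
#' A structure model is a list with an `identifier` and an `atoms` data frame
#' holding one row per atom: `record` ("ATOM"/"HETATM"), `chain_id`,
#' `residue_number` (author numbering), `residue_name` (3-letter code),
#' `atom_name`, `element`, `altloc`, `occupancy`, `x`, `y`, `z` (Angstrom).
#'
#' @param atoms Atom data frame as described above.
#' @param identifier Text identifier (e.g. PDB code or file stem).
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, identifier = "model") {
  required <- c("record", "chain_id", "residue_number", "residue_name",
                "atom_name", "element", "altloc", "occupancy", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("empty model", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom positions must be finite", call. = FALSE)
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
    warning("occupancies outside [0, 1] present")
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, atoms$altloc)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom, altloc) records in model", call. = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, chains %s, residues %d-%d\n",
              x$identifier, nrow(x$atoms),
              paste(unique(x$atoms$chain_id), collapse = ","),
              min(x$atoms$residue_number), max(x$atoms$residue_number)))
  invisible(x)
}

#' Domain definition by residue-number ranges
#'
#' Inclusive author-numbered residue intervals for the cap and core domains.
#' The default matches beta-phosphoglucomutase: cap T16-V87, core M1-D15 plus
#' S88-K221.
#'
#' @param cap_ranges,core_ranges Two-column matrices (start, end) or range
#'   strings such as `"16-87"` / `"1-15,88-221"`.
#' @return A `domain_definition` object.
#' @export
domain_definition <- function(cap_ranges = "16-87", core_ranges = "1-15,88-221") {
  cap <- parse_ranges(cap_ranges)
  core <- parse_ranges(core_ranges)
  cap_res <- ranges_to_residues(cap)
  core_res <- ranges_to_residues(core)
  if (length(intersect(cap_res, core_res))) {
    stop("cap and core residue ranges overlap", call. = FALSE)
  }
  structure(list(cap_ranges = cap, core_ranges = core), class = "domain_definition")
}

#' Parse a residue-range string
#'
#' Accepts strings like `"16-87"` or `"1-15,88-221"` (inclusive, 1-based,
#' author numbering) or a two-column numeric matrix.
#'
#' @param x Range string or matrix.
#' @return Two-column integer matrix with columns `start`, `end`.
#' @export
parse_ranges <- function(x) {
  if (is.matrix(x)) {
    m <- matrix(as.integer(x), ncol = 2)
  } else if (is.character(x)) {
    parts <- trimws(unlist(strsplit(paste(x, collapse = ","), ",")))
    parts <- parts[nzchar(parts)]
    if (!length(parts)) stop("empty range specification", call. = FALSE)
    m <- t(vapply(parts, function(p) {
      if (grepl("^-?[0-9]+$", p)) return(rep(as.integer(p), 2))
      hit <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      if (length(hit) != 3) stop("cannot parse residue range: '", p, "'", call. = FALSE)
      as.integer(hit[2:3])
    }, integer(2)))
  } else {
    stop("ranges must be a string or a two-column matrix", call. = FALSE)
  }
  if (any(m[, 2] < m[, 1])) stop("range end precedes start", call. = FALSE)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

ranges_to_residues <- function(m) {
  unique(unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2])))
}

#' Read a macromolecular structure
#'
#' Reads PDB (via [bio3d::read.pdb()]) or mmCIF (via [bio3d::read.cif()])
#' files, preserving author residue numbering and both ATOM and HETATM
#' records. Multi-model files yield the first model with a warning.
#'
#' @param path File path.
#' @param dialect `"pdb"` or `"mmcif"` (mmCIF is read-only).
#' @param identifier Model identifier; defaults to the file stem.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"), identifier = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    if (dialect == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", dialect, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model: ", path, call. = FALSE)
  if (dialect == "pdb") {
    n_models <- length(grep("^MODEL", readLines(path, warn = FALSE)))
    if (n_models > 1L) warning("multi-model file: using first model only")
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  atoms <- data.frame(record = at$type,
                      chain_id = ifelse(is.na(at$chain), "A", at$chain),
                      residue_number = at$resno,
                      residue_name = at$resid,
                      atom_name = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       guess_element(at$elety), at$elesy),
                      altloc = alt,
                      occupancy = occ,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (is.null(identifier)) identifier <- sub("\\.[^.]*$", "", basename(path))
  structure_model(atoms, identifier = identifier)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  ifelse(nchar(nm) > 0, substr(nm, 1, 1), "X")
}

#' Write a structure model as PDB
#'
#' Emits fixed-column (v3.3) ATOM/HETATM records; coordinates are written to
#' 3 decimal places so a read/write round trip preserves them to 0.001 A.
#' Residue numbers above 9999 are not representable in the fixed columns and
#' raise an error (no hybrid-36 extension).
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (any(at$residue_number > 9999 | at$residue_number < -999)) {
    stop("residue numbers outside the PDB fixed-column range (-999..9999)",
         call. = FALSE)
  }
  name4 <- ifelse(nchar(at$atom_name) >= 4, substr(at$atom_name, 1, 4),
                  sprintf(" %-3s", at$atom_name))
  lines <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   at$record, seq_len(nrow(at)) %% 100000L, name4, at$altloc,
                   at$residue_name, at$chain_id, at$residue_number, "",
                   at$x, at$y, at$z, at$occupancy, 0, at$element)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

is_hydrogen <- function(atoms) {
  toupper(atoms$element) %in% c("H", "D") |
    grepl("^[0-9]*[HD]", toupper(trimws(atoms$atom_name)))
}

filter_atoms <- function(atoms, atom_filter = c("ca_only", "non_h", "all"),
                         include_hetatm = FALSE) {
  atom_filter <- match.arg(atom_filter)
  keep <- rep(TRUE, nrow(atoms))
  if (!include_hetatm) keep <- keep & atoms$record == "ATOM"
  # altloc policy: keep blank or 'A' only (deterministic); log when dropped
  alt_drop <- !(atoms$altloc %in% c("", "A"))
  if (any(alt_drop & keep)) {
    message(sum(alt_drop & keep), " alternate-location atoms dropped (kept blank/'A')")
  }
  keep <- keep & !alt_drop
  if (atom_filter == "ca_only") {
    keep <- keep & trimws(atoms$atom_name) == "CA" & !is_hydrogen(atoms)
  } else if (atom_filter == "non_h") {
    keep <- keep & !is_hydrogen(atoms)
  }
  atoms[keep, , drop = FALSE]
}

#' Select domain coordinates from a model
#'
#' Returns the coordinates of the cap or core domain of one chain, ordered by
#' residue number then atom name. HETATM records (ligands, ions, waters) are
#' excluded unless `include_hetatm = TRUE`; alternate locations other than
#' blank/'A' are dropped. Residues of the definition missing from the model
#' are silently omitted and recorded in the `missing_residues` attribute.
#'
#' @param model A [structure_model()].
#' @param domains A [domain_definition()].
#' @param which `"cap"` or `"core"`.
#' @param atom_filter `"ca_only"` (default), `"non_h"` or `"all"`.
#' @param chain Chain identifier; defaults to the first chain in the model.
#' @param include_hetatm Include HETATM records (default `FALSE`).
#' @return List with `xyz` (n x 3 matrix), `atoms` (identity data frame) and
#'   attribute-style entry `missing_residues`.
#' @export
select_domain_coords <- function(model, domains = domain_definition(),
                                 which = c("cap", "core"),
                                 atom_filter = c("ca_only", "non_h", "all"),
                                 chain = NULL, include_hetatm = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  which <- match.arg(which)
  atom_filter <- match.arg(atom_filter)
  at <- model$atoms
  if (is.null(chain)) chain <- at$chain_id[1]
  if (!chain %in% at$chain_id) {
    stop("chain '", chain, "' not present in model '", model$identifier, "'",
         call. = FALSE)
  }
  at <- at[at$chain_id == chain, , drop = FALSE]
  at <- filter_atoms(at, atom_filter, include_hetatm)
  res <- ranges_to_residues(if (which == "cap") domains$cap_ranges else domains$core_ranges)
  sel <- at[at$residue_number %in% res, , drop = FALSE]
  sel <- sel[order(sel$residue_number, sel$atom_name), , drop = FALSE]
  if (nrow(sel) < 3L) stop("degenerate selection: fewer than 3 atoms", call. = FALSE)
  list(xyz = as.matrix(sel[, c("x", "y", "z")]),
       atoms = sel,
       missing_residues = sort(setdiff(res, sel$residue_number)))
}

#' Pair atoms shared by two models
#'
#' Matches atoms between two models on (residue_number, atom_name) within the
#' requested chains; residues whose residue names disagree (point mutants)
#' are excluded from the pairing and reported. Returns equal-length
#' coordinate lists in the same order.
#'
#' @param a,b [structure_model()] objects.
#' @param atom_filter `"non_h"` (default), `"ca_only"` or `"all"`.
#' @param chain_a,chain_b Chain identifiers (default: first chain of each).
#' @param residues Optional integer vector restricting the pairing to those
#'   residue numbers (e.g. one domain).
#' @param include_hetatm Include HETATM records (default `FALSE`).
#' @return List with `xyz_a`, `xyz_b` (n x 3 matrices), `atoms` (shared
#'   identities) and `excluded_residues` (mismatched residue names).
#' @export
pair_shared_atoms <- function(a, b, atom_filter = c("non_h", "ca_only", "all"),
                              chain_a = NULL, chain_b = NULL, residues = NULL,
                              include_hetatm = FALSE) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  atom_filter <- match.arg(atom_filter)
  take <- function(model, chain) {
    at <- model$atoms
    if (is.null(chain)) chain <- at$chain_id[1]
    if (!chain %in% at$chain_id) {
      stop("chain '", chain, "' not present in model '", model$identifier, "'",
           call. = FALSE)
    }
    at <- filter_atoms(at[at$chain_id == chain, , drop = FALSE],
                       atom_filter, include_hetatm)
    if (!is.null(residues)) at <- at[at$residue_number %in% residues, , drop = FALSE]
    at
  }
  at_a <- take(a, chain_a)
  at_b <- take(b, chain_b)
  key_a <- paste(at_a$residue_number, trimws(at_a$atom_name))
  key_b <- paste(at_b$residue_number, trimws(at_b$atom_name))
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  # residue-name mismatch at a shared number (e.g. D10N): exclude that residue
  mismatch <- at_a$residue_number[ia][at_a$residue_name[ia] != at_b$residue_name[ib]]
  mismatch <- sort(unique(mismatch))
  if (length(mismatch)) {
    message("excluding residues with mismatched names: ",
            paste(mismatch, collapse = ", "))
    keep <- !(at_a$residue_number[ia] %in% mismatch)
    ia <- ia[keep]; ib <- ib[keep]
  }
  ord <- order(at_a$residue_number[ia], trimws(at_a$atom_name[ia]))
  ia <- ia[ord]; ib <- ib[ord]
  if (length(ia) < 3L) stop("fewer than 3 shared atoms", call. = FALSE)
  list(xyz_a = as.matrix(at_a[ia, c("x", "y", "z")]),
       xyz_b = as.matrix(at_b[ib, c("x", "y", "z")]),
       atoms = at_a[ia, c("chain_id", "residue_number", "residue_name", "atom_name")],
       excluded_residues = mismatch)
}

#' Apply a rigid transform to a whole model
#'
#' @param model A [structure_model()].
#' @param transform A [rigid_transform()].
#' @return The transformed [structure_model()].
#' @export
transform_structure <- function(model, transform) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- apply_transform(transform, as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
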