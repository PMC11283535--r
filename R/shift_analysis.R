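# Chemical-shift analysis: shift tables, weighted chemical-shift
# perturbations (CSP), the reporter-residue library, state classification
# and correlation-based species identification.

#' Nitrogen weight used throughout the shift analysis
#'
#' Amide 15N shift differences are scaled by 0.13 relative to 1HN both in the
#' weighted CSP formula and in the 2-D classification distance, so a single
#' metric governs both analyses.
#' @export
CSP_N_WEIGHT <- 0.13

#' Construct a chemical-shift table
#'
#' One record per residue: `residue_number`, `residue_type` (1-letter code),
#' `delta_HN` (ppm), `delta_N` (ppm) and optional `delta_CB` (ppm). Amide
#' shifts are soft-validated (1HN in 5-12 ppm, 15N in 100-140 ppm; values
#' outside warn but are kept).
#'
#' @param records Data frame with the columns above (`delta_CB` optional).
#' @param species_label Text label of the species.
#' @param accession Optional accession (e.g. a BMRB id).
#' @return A `shift_table` object.
#' @export
shift_table <- function(records, species_label = "species", accession = NA_character_) {
  required <- c("residue_number", "residue_type", "delta_HN", "delta_N")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("shift table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$residue_number)) {
    stop("duplicate residue numbers in shift table", call. = FALSE)
  }
  if (!"delta_CB" %in% names(records)) records$delta_CB <- NA_real_
  hn <- records$delta_HN
  nn <- records$delta_N
  if (any(!is.na(hn) & (hn < 5 | hn > 12))) {
    warning("1HN shifts outside the typical 5-12 ppm amide window")
  }
  if (any(!is.na(nn) & (nn < 100 | nn > 140))) {
    warning("15N shifts outside the typical 100-140 ppm amide window")
  }
  records <- as.data.frame(records[order(records$residue_number),
                                   c(required, "delta_CB")],
                           stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(species_label = species_label, accession = accession,
                 records = records),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("shift_table '%s'%s: %d residues (%d with 13CB)\n",
              x$species_label,
              if (is.na(x$accession)) "" else paste0(" [", x$accession, "]"),
              nrow(x$records), sum(!is.na(x$records$delta_CB))))
  invisible(x)
}

#' Read a chemical-shift table
#'
#' CSV format: columns `residue_number`, `residue_type`, `delta_HN_ppm`,
#' `delta_N_ppm`, optional `delta_CB_ppm`. NMR-STAR 3.1 ingestion extracts
#' backbone H/N (and CB) rows from the `Atom_chem_shift` loop.
#'
#' @param path File path.
#' @param format `"csv"` or `"nmrstar"`.
#' @param species_label Species label (default: file stem).
#' @param accession Optional accession string.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, format = c("csv", "nmrstar"),
                             species_label = NULL, accession = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(species_label)) species_label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("residue_number", "residue_type", "delta_HN_ppm", "delta_N_ppm")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols)) {
      stop("missing required columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    rec <- data.frame(residue_number = as.integer(df$residue_number),
                      residue_type = as.character(df$residue_type),
                      delta_HN = as.numeric(df$delta_HN_ppm),
                      delta_N = as.numeric(df$delta_N_ppm),
                      delta_CB = if ("delta_CB_ppm" %in% names(df))
                        as.numeric(df$delta_CB_ppm) else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    rec <- parse_nmrstar_shifts(path)
  }
  shift_table(rec, species_label = species_label, accession = accession)
}

# Minimal NMR-STAR 3.1 reader for the Atom_chem_shift loop: collects H, N
# and CB rows per residue. Only the tags needed here are interpreted.
parse_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- grep("^\\s*loop_\\s*$", lines)
  for (start in i) {
    j <- start + 1L
    tags <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, trimws(lines[j]))
      j <- j + 1L
    }
    if (!any(grepl("_Atom_chem_shift\\.", tags))) next
    want <- function(tag) {
      hit <- grep(paste0("_Atom_chem_shift\\.", tag, "$"), tags)
      if (!length(hit)) stop("NMR-STAR loop lacks tag _Atom_chem_shift.", tag,
                             call. = FALSE)
      hit[1]
    }
    k_seq <- want("Seq_ID"); k_comp <- want("Comp_ID")
    k_atom <- want("Atom_ID"); k_val <- want("Val")
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "stop_" || ln == "") break
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) >= max(k_seq, k_comp, k_atom, k_val)) {
        rows[[length(rows) + 1L]] <- c(f[k_seq], f[k_comp], f[k_atom], f[k_val])
      }
      j <- j + 1L
    }
    if (!length(rows)) stop("empty Atom_chem_shift loop", call. = FALSE)
    m <- do.call(rbind, rows)
    resno <- as.integer(m[, 1])
    comp <- m[, 2]
    atom <- toupper(m[, 3])
    val <- as.numeric(m[, 4])
    res <- sort(unique(resno))
    get <- function(which_atom) {
      v <- rep(NA_real_, length(res))
      hit <- atom == which_atom
      v[match(resno[hit], res)] <- val[hit]
      v
    }
    one_letter <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
    typ <- one_letter[toupper(comp[match(res, resno)])]
    typ[is.na(typ)] <- "X"
    return(data.frame(residue_number = res,
                      residue_type = unname(typ),
                      delta_HN = get("H"),
                      delta_N = get("N"),
                      delta_CB = get("CB"),
                      stringsAsFactors = FALSE))
  }
  stop("no Atom_chem_shift loop found in ", path, call. = FALSE)
}

#' Write a chemical-shift table as CSV
#'
#' @param table A [shift_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_shift_table <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  df <- table$records
  names(df) <- c("residue_number", "residue_type", "delta_HN_ppm",
                 "delta_N_ppm", "delta_CB_ppm")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# weighted 2-D amide distance; falls back to the dimensions present
weighted_shift_distance <- function(dHN, dN) {
  ifelse(is.na(dN), abs(dHN),
         ifelse(is.na(dHN), CSP_N_WEIGHT * abs(dN),
                sqrt(dHN^2 + (CSP_N_WEIGHT * dN)^2)))
}

#' Weighted chemical-shift perturbation profile
#'
#' Per shared residue, the weighted backbone-amide perturbation
#' `Delta delta = sqrt((dHN_X - dHN_Y)^2 + (0.13 (dN_X - dN_Y))^2)` between
#' two species. Residues missing in either table are absent from the
#' profile, not zero.
#'
#' @param x,y [shift_table()] objects for the two species compared.
#' @return A `data.frame` (class `csp_profile`) with `residue_number`,
#'   `residue_type`, `delta_delta` (ppm) plus the comparison labels in
#'   attributes `species_x`/`species_y`.
#' @export
weighted_csp <- function(x, y) {
  stopifnot(inherits(x, "shift_table"), inherits(y, "shift_table"))
  shared <- merge(x$records, y$records, by = "residue_number",
                  suffixes = c("_x", "_y"))
  shared <- shared[!is.na(shared$delta_HN_x) & !is.na(shared$delta_HN_y) &
                     !is.na(shared$delta_N_x) & !is.na(shared$delta_N_y), ]
  if (nrow(shared) == 0L) stop("no shared residues between shift tables", call. = FALSE)
  dd <- sqrt((shared$delta_HN_x - shared$delta_HN_y)^2 +
               (CSP_N_WEIGHT * (shared$delta_N_x - shared$delta_N_y))^2)
  out <- data.frame(residue_number = shared$residue_number,
                    residue_type = shared$residue_type_x,
                    delta_delta = dd, stringsAsFactors = FALSE)
  out <- out[order(out$residue_number), ]
  rownames(out) <- NULL
  attr(out, "species_x") <- x$species_label
  attr(out, "species_y") <- y$species_label
  class(out) <- c("csp_profile", class(out))
  out
}

#' Read a reporter-residue library
#'
#' Tab- or comma-separated text with columns `reporter` (e.g. `"A143"`,
#' `"P146-CB"`), `state`, `delta_HN_ppm`, `delta_N_ppm`, `delta_CB_ppm`
#' (amide columns may be empty for 13CB-only reporters). Each row is one
#' labelled cluster point.
#'
#' @param path File path; defaults to the partial library shipped with the
#'   package, which contains only literature-printed reporter coordinates.
#' @return Data frame with the columns above plus `residue_number`.
#' @export
read_reporter_library <- function(path = system.file("extdata", "reporter_library.tsv",
                                                     package = "allomorph")) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  required <- c("reporter", "state", "delta_HN_ppm", "delta_N_ppm", "delta_CB_ppm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("library missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$residue_number <- as.integer(gsub("[^0-9]", "", sub("-.*$", "", df$reporter)))
  df
}

# nearest labelled cluster point for one reporter residue
nearest_state <- function(record, lib_points) {
  d <- weighted_shift_distance(record$delta_HN - lib_points$delta_HN_ppm,
                               record$delta_N - lib_points$delta_N_ppm)
  ord <- order(d)
  list(state = as.character(lib_points$state[ord[1]]), distance = d[ord[1]])
}

classify_by_reporters <- function(table, library, reporters, cutoff) {
  stopifnot(inherits(table, "shift_table"))
  lib <- library[sub("-.*$", "", library$reporter) %in% reporters &
                   !is.na(library$delta_HN_ppm), , drop = FALSE]
  evidence <- list()
  for (rep_name in reporters) {
    resno <- as.integer(gsub("[^0-9]", "", rep_name))
    lp <- lib[sub("-.*$", "", lib$reporter) == rep_name, , drop = FALSE]
    rec <- table$records[table$records$residue_number == resno, , drop = FALSE]
    if (nrow(lp) == 0L || nrow(rec) == 0L || is.na(rec$delta_HN)) next
    ns <- nearest_state(rec, lp)
    evidence[[length(evidence) + 1L]] <-
      data.frame(reporter = rep_name, state = ns$state, distance = ns$distance,
                 stringsAsFactors = FALSE)
  }
  if (!length(evidence)) {
    stop("none of the reporters (", paste(reporters, collapse = ", "),
         ") are present in both table and library", call. = FALSE)
  }
  ev <- do.call(rbind, evidence)
  states <- unique(ev$state)
  label <- if (length(states) == 1L && all(ev$distance <= cutoff)) states else "ambiguous"
  list(state = label, evidence = ev)
}

#' Classify the peptide-bond isomerisation state from reporter residues
#'
#' A143 and D180 amide shifts report the cis/trans state of the K145-X146
#' peptide bond: the table's shifts at each reporter are assigned to the
#' nearest labelled library cluster under the weighted amide distance.
#' The overall call requires reporter agreement within `cutoff`; otherwise
#' `"ambiguous"`.
#'
#' @param table A [shift_table()].
#' @param library Reporter library data frame ([read_reporter_library()]).
#' @param reporters Reporter residue names (default A143, D180).
#' @param cutoff Ambiguity distance cutoff in ppm (default 0.25).
#' @return List with `state` (`"cis"`, `"trans"` or `"ambiguous"`) and the
#'   per-reporter `evidence` table.
#' @export
classify_isomer_state <- function(table, library, reporters = c("A143", "D180"),
                                  cutoff = 0.25) {
  classify_by_reporters(table, library, reporters, cutoff)
}

#' Classify the interdomain hinge-closure state from reporter residues
#'
#' I84 and S88 amide shifts track the hinge-closure angle through open,
#' NAC I, NAC III and fully closed states. Within the NAC III region the
#' I84 1HN sub-rule separates NAC III (~7.00 ppm) from its twisted variant
#' NAC III-t (~7.17 ppm) at the midpoint boundary (default 7.085 ppm).
#'
#' @inheritParams classify_isomer_state
#' @param reporters Reporter residue names (default I84, S88).
#' @param i84_boundary 1HN boundary (ppm) separating NAC_III from NAC_III_t.
#' @return List with `state` (one of `open`, `NAC_I`, `NAC_III`,
#'   `NAC_III_t`, `closed`, `ambiguous`) and the `evidence` table.
#' @export
classify_closure_state <- function(table, library, reporters = c("I84", "S88"),
                                   cutoff = 0.25, i84_boundary = 7.085) {
  out <- classify_by_reporters(table, library, reporters, cutoff)
  nac_like <- c("NAC_III", "NAC_III_t")
  ev_states <- out$evidence$state
  # reporters that only disagree within the NAC III family still agree on the
  # family; resolve the t-distinction by the I84 1HN sub-rule
  family_call <- out$state %in% nac_like ||
    (out$state == "ambiguous" && all(ev_states %in% nac_like) &&
       all(out$evidence$distance <= cutoff))
  if (family_call) {
    rec <- table$records[table$records$residue_number == 84L, , drop = FALSE]
    if (nrow(rec) == 1L && !is.na(rec$delta_HN)) {
      out$state <- if (rec$delta_HN < i84_boundary) "NAC_III" else "NAC_III_t"
    }
  }
  out
}

#' Classify the proline isomer from its 13C-beta shift
#'
#' Cis-proline 13CB resonates near 35.0 ppm, trans-proline near 32.0 ppm;
#' values within `tol` of either reference are assigned, anything between is
#' `"ambiguous"`.
#'
#' @param delta_CB 13CB chemical shift, ppm.
#' @param cis_ref,trans_ref Reference shifts, ppm.
#' @param tol Assignment tolerance, ppm (default 1.0).
#' @return `"cis"`, `"trans"` or `"ambiguous"`.
#' @export
classify_proline_isomer <- function(delta_CB, cis_ref = 35.0, trans_ref = 32.0,
                                    tol = 1.0) {
  if (!is.finite(delta_CB)) stop("delta_CB must be finite", call. = FALSE)
  if (abs(delta_CB - cis_ref) <= tol) "cis"
  else if (abs(delta_CB - trans_ref) <= tol) "trans"
  else "ambiguous"
}

#' Detect transient magnesium (MgT) occupancy from the A115 amide proton
#'
#' The backbone amide proton of A115 moves upfield by ~1.6 ppm when the
#' transient magnesium site is occupied. The reported displacement is
#' `delta_HN(reference) - delta_HN(table)`; occupancy is called when it
#' exceeds `threshold` (default 0.8 ppm, half the library displacement).
#'
#' @param table A [shift_table()] for the species under test.
#' @param reference_table A [shift_table()] for an MgT-free reference.
#' @param residue Reporter residue number (default 115).
#' @param threshold Displacement threshold, ppm.
#' @return List with `state` (`"MgT_bound"`, `"MgT_free"` or
#'   `"indeterminate"`) and `displacement` (ppm, upfield positive).
#' @export
detect_mgt <- function(table, reference_table, residue = 115L, threshold = 0.8) {
  stopifnot(inherits(table, "shift_table"), inherits(reference_table, "shift_table"))
  a <- table$records[table$records$residue_number == residue, , drop = FALSE]
  b <- reference_table$records[reference_table$records$residue_number == residue, ,
                               drop = FALSE]
  if (nrow(a) != 1L || nrow(b) != 1L || is.na(a$delta_HN) || is.na(b$delta_HN)) {
    return(list(state = "indeterminate", displacement = NA_real_))
  }
  disp <- b$delta_HN - a$delta_HN
  list(state = if (disp > threshold) "MgT_bound" else "MgT_free",
       displacement = disp)
}

#' Fisher z-test for two independent Pearson correlations
#'
#' Transforms each correlation with `atanh` (Fisher z, equal to
#' `0.5 * log((1 + r)/(1 - r))`) and compares them with the two-sample
#' statistic `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, with a two-sided
#' p-value from the standard normal.
#'
#' @param r1,r2 Pearson correlation coefficients, |r| < 1.
#' @param n1,n2 Sample sizes, each > 3.
#' @return List with `z` and `p`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("|r| = 1 gives an infinite Fisher transform", call. = FALSE)
  }
  if (any(c(n1, n2) <= 3)) stop("n must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Rank candidate species by chemical-shift correlation with a query
#'
#' For each candidate, Pearson correlations of the 1HN (`r_H`) and 15N
#' (`r_N`) shifts over the residues shared with the query, ranked by the
#' conservative statistic `min(r_H, r_N)`. Each non-top candidate also
#' carries a Fisher z-test of its `min(r_H, r_N)` against the top-ranked
#' candidate's.
#'
#' @param query A [shift_table()].
#' @param candidates Named list of [shift_table()] objects.
#' @param min_shared Minimum shared residues per candidate (default 4).
#' @return Data frame with columns `candidate`, `r_H`, `r_N`, `n`, `z`, `p`,
#'   ranked best first.
#' @export
correlation_match <- function(query, candidates, min_shared = 4L) {
  stopifnot(inherits(query, "shift_table"), length(candidates) > 0L)
  nm <- names(candidates)
  if (is.null(nm)) nm <- vapply(candidates, function(x) x$species_label, "")
  rows <- list()
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    shared <- merge(query$records, cand$records, by = "residue_number",
                    suffixes = c("_q", "_c"))
    shared <- shared[stats::complete.cases(shared[, c("delta_HN_q", "delta_HN_c",
                                                      "delta_N_q", "delta_N_c")]), ]
    if (nrow(shared) < min_shared) next
    rows[[length(rows) + 1L]] <-
      data.frame(candidate = nm[i],
                 r_H = cor(shared$delta_HN_q, shared$delta_HN_c),
                 r_N = cor(shared$delta_N_q, shared$delta_N_c),
                 n = nrow(shared), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no candidate shares at least ", min_shared, " residues with the query",
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$r_min <- pmin(tab$r_H, tab$r_N)
  tab <- tab[order(-tab$r_min), , drop = FALSE]
  tab$z <- NA_real_
  tab$p <- NA_real_
  if (nrow(tab) > 1L && abs(tab$r_min[1]) < 1) {
    for (i in 2:nrow(tab)) {
      if (abs(tab$r_min[i]) < 1) {
        ft <- fisher_z_test(tab$r_min[1], tab$n[1], tab$r_min[i], tab$n[i])
        tab$z[i] <- ft$z
        tab$p[i] <- ft$p
      }
    }
  }
  rownames(tab) <- NULL
  tab
}
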