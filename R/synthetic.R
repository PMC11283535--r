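# Ground-truthed synthetic data: two-domain C-alpha structures with a known
# cap rotation, multi-species shift tables drawn from a reporter library,
# and multi-species intensity tables at known populations. Every generator
# is a pure function of its parameters and seed.

# idealised alpha-helical C-alpha trace: rise 1.5 A, radius 2.3 A,
# 100 degrees of rotation per residue, axis along +x
ideal_helix <- function(n, rise = 1.5, radius = 2.3, turn_deg = 100) {
  i <- seq_len(n) - 1
  th <- deg2rad(turn_deg) * i
  cbind(x = rise * i, y = radius * cos(th), z = radius * sin(th))
}

# antiparallel four-helix bundle on a sep_y x sep_z grid. A single straight
# helix has a rotationally degenerate cross-section; a bundle with unequal
# grid spacings gives three well-separated principal variances, so both the
# principal-axes frame and superpositions are well conditioned.
helix_bundle <- function(n, n_seg = 4L, sep_y = 18, sep_z = 12) {
  sizes <- rep(n %/% n_seg, n_seg)
  if (n %% n_seg) sizes[seq_len(n %% n_seg)] <- sizes[seq_len(n %% n_seg)] + 1L
  segs <- lapply(seq_len(n_seg), function(k) {
    h <- ideal_helix(sizes[k])
    if (k %% 2L == 0L) h[, 1] <- max(h[, 1]) - h[, 1]  # antiparallel
    h[, 2] <- h[, 2] + ((k - 1L) %% 2L) * sep_y
    h[, 3] <- h[, 3] + ((k - 1L) %/% 2L) * sep_z
    h
  })
  out <- do.call(rbind, segs)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Generate a two-domain C-alpha structure with a known cap rotation
#'
#' Builds an idealised C-alpha model in which cap and core are each an
#' antiparallel four-helix bundle of standard alpha-helices (rise 1.5 A,
#' radius 2.3 A, 100 degrees per residue), numbered to
#' beta-phosphoglucomutase-like ranges (cap from residue 16, core
#' as residues 1-15 plus 88 onwards) so the default [domain_definition()]
#' applies unchanged at the default sizes. The assembled reference is
#' canonicalised onto its cap principal axes; the returned structure is then
#' produced by rotating the cap by exactly `rotation_from_euler(angles)`
#' about the hinge point (the C-alpha of the core residue preceding the cap)
#' within that canonical frame, and adding isotropic Gaussian coordinate
#' noise to all atoms. The motion pipeline therefore recovers `angles`
#' exactly in the noise-free case.
#'
#' @param n_cap,n_core Residue counts (>= 10; defaults 72 and 149 mimic the
#'   cap 16-87 / core 1-15, 88-221 split).
#' @param angles An [euler_angles()] (or list with pitch/roll/yaw in degrees).
#' @param noise_sigma Isotropic Gaussian coordinate noise SD, Angstrom.
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @return List with `model` (the rotated, noisy structure), `reference`
#'   (the canonical zero-angle structure), `domains` (the matching
#'   [domain_definition()]) and `ground_truth` (applied angles, convention,
#'   noise sigma, seed).
#' @export
make_two_domain_structure <- function(n_cap = 72L, n_core = 149L,
                                      angles = euler_angles(0, 0, 0),
                                      noise_sigma = 0, seed = 1L) {
  if (n_cap < 10L || n_core < 10L) stop("need at least 10 residues per domain",
                                        call. = FALSE)
  if (!is.list(angles) || !all(c("pitch", "roll", "yaw") %in% names(angles))) {
    stop("angles must be an euler_angles object or compatible list", call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be a non-negative number", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)

  # both domains are antiparallel four-helix bundles; the cap is lifted in z
  # and shifted so the two domains form an open two-lobed arrangement
  core_xyz <- helix_bundle(n_core)
  cap_xyz <- sweep(helix_bundle(n_cap), 2, c(8, 0, 34), "+")

  # beta-PGM-like author numbering: core leads with residues 1..15, the cap
  # occupies 16..(15+n_cap), the core resumes at 88 or directly after the cap
  n_lead <- min(15L, n_core)
  cap_start <- n_lead + 1L
  core_resume <- max(88L, cap_start + n_cap)
  core_resno <- c(seq_len(n_lead),
                  seq(core_resume, length.out = n_core - n_lead))
  cap_resno <- seq(cap_start, length.out = n_cap)

  build <- function(core_xyz, cap_xyz, id) {
    xyz <- rbind(core_xyz[seq_len(n_lead), , drop = FALSE],
                 cap_xyz,
                 core_xyz[setdiff(seq_len(n_core), seq_len(n_lead)), , drop = FALSE])
    resno <- c(core_resno[seq_len(n_lead)], cap_resno,
               core_resno[-seq_len(n_lead)])
    structure_model(data.frame(record = "ATOM", chain_id = "A",
                               residue_number = resno, residue_name = "ALA",
                               atom_name = "CA", element = "C", altloc = "",
                               occupancy = 1,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               stringsAsFactors = FALSE),
                    identifier = id)
  }

  domains <- domain_definition(
    sprintf("%d-%d", cap_start, cap_start + n_cap - 1L),
    sprintf("1-%d,%d-%d", n_lead, core_resume, core_resume + (n_core - n_lead) - 1L))

  reference <- canonicalize_reference(build(core_xyz, cap_xyz, "synthetic_ref"),
                                      domains)

  # rotate the cap about the hinge point within the canonical frame
  ref_at <- reference$atoms
  cap_rows <- ref_at$residue_number %in% cap_resno
  hinge <- unlist(ref_at[ref_at$residue_number == n_lead, c("x", "y", "z")])
  R <- rotation_from_euler(angles)
  cap_new <- sweep(as.matrix(ref_at[cap_rows, c("x", "y", "z")]), 2, hinge) %*% t(R)
  cap_new <- sweep(cap_new, 2, hinge, "+")
  at <- ref_at
  at[cap_rows, c("x", "y", "z")] <- cap_new

  if (noise_sigma > 0) {
    set.seed(seed)
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
      matrix(rnorm(3L * nrow(at), sd = noise_sigma), ncol = 3)
  }
  model <- structure_model(at, identifier = sprintf("synthetic_p%g_r%g_y%g",
                                                    angles$pitch, angles$roll,
                                                    angles$yaw))
  list(model = model, reference = reference, domains = domains,
       ground_truth = list(pitch = angles$pitch, roll = angles$roll,
                           yaw = angles$yaw,
                           convention = angles$convention %||% "xyz",
                           noise_sigma = noise_sigma, seed = seed,
                           hinge_residue = n_lead))
}

#' Synthetic reporter-residue library
#'
#' A fully populated reporter library for simulation and testing. The
#' literature-printed coordinates are used where available (I84 1HN 7.00 ppm
#' for NAC III vs 7.17 ppm for NAC III-t; P146 13CB 35.0 ppm cis / 32.0 ppm
#' trans; A115 1.6 ppm upfield on MgT binding); all other cluster points are
#' synthetic placeholders with realistic amide-window values, clearly
#' separated per state.
#'
#' @return Reporter-library data frame (see [read_reporter_library()]).
#' @export
synthetic_reporter_library <- function() {
  df <- rbind(
    # isomer-state reporters (invented, well-separated clusters)
    data.frame(reporter = "A143", state = c("cis", "trans"),
               delta_HN_ppm = c(8.30, 7.85), delta_N_ppm = c(123.5, 121.0),
               delta_CB_ppm = NA_real_),
    data.frame(reporter = "D180", state = c("cis", "trans"),
               delta_HN_ppm = c(8.65, 8.20), delta_N_ppm = c(118.0, 120.5),
               delta_CB_ppm = NA_real_),
    # hinge-closure reporters; I84 NAC III / NAC III-t 1HN values are the
    # printed ones, other coordinates synthetic
    data.frame(reporter = "I84",
               state = c("open", "NAC_I", "NAC_III", "NAC_III_t", "closed"),
               delta_HN_ppm = c(7.60, 7.35, 7.00, 7.17, 6.75),
               delta_N_ppm = c(117.5, 119.0, 120.8, 121.6, 122.8),
               delta_CB_ppm = NA_real_),
    data.frame(reporter = "S88",
               state = c("open", "NAC_I", "NAC_III", "NAC_III_t", "closed"),
               delta_HN_ppm = c(8.90, 8.60, 8.30, 8.38, 8.00),
               delta_N_ppm = c(115.0, 116.5, 118.0, 118.4, 119.5),
               delta_CB_ppm = NA_real_),
    # MgT occupancy reporter: bound 1.6 ppm upfield of free (printed value)
    data.frame(reporter = "A115", state = c("MgT_free", "MgT_bound"),
               delta_HN_ppm = c(8.50, 6.90), delta_N_ppm = c(124.0, 124.3),
               delta_CB_ppm = NA_real_),
    # proline 13CB reporter (printed cis value)
    data.frame(reporter = "P146-CB", state = c("cis", "trans"),
               delta_HN_ppm = NA_real_, delta_N_ppm = NA_real_,
               delta_CB_ppm = c(35.0, 32.0)))
  df$residue_number <- as.integer(gsub("[^0-9]", "", sub("-.*$", "", df$reporter)))
  df
}

#' Generate shift tables for multiple coexisting species
#'
#' Each species' reporter residues take the library cluster point of the
#' state requested for it, plus Gaussian shift noise; all non-reporter
#' residues share a per-residue random baseline across species (so shifts of
#' different species correlate highly except where their states differ),
#' again plus noise. 15N noise is scaled by the inverse nitrogen weight so
#' the noise is isotropic in the weighted distance metric.
#'
#' @param library Reporter library ([synthetic_reporter_library()] or
#'   [read_reporter_library()]); must cover every requested state.
#' @param species_states Named list: one entry per species, each a named
#'   character vector mapping reporter group to state, e.g.
#'   `list(A = c(isomer = "cis", closure = "NAC_III", mgt = "MgT_free"))`.
#' @param noise_sigma_ppm 1HN-equivalent Gaussian noise SD, ppm.
#' @param n_residues Total residues per table (default 221).
#' @param seed Integer seed.
#' @return List with `tables` (named list of [shift_table()]) and
#'   `ground_truth` (requested states, noise, seed).
#' @export
make_species_shift_tables <- function(library = synthetic_reporter_library(),
                                      species_states,
                                      noise_sigma_ppm = 0,
                                      n_residues = 221L, seed = 1L) {
  stopifnot(is.list(species_states), length(species_states) > 0L)
  groups <- list(isomer = c("A143", "D180"), closure = c("I84", "S88"),
                 mgt = "A115")
  # validate library coverage for every requested state
  for (sp in names(species_states)) {
    st <- species_states[[sp]]
    for (g in names(st)) {
      if (!g %in% names(groups)) stop("unknown reporter group: ", g, call. = FALSE)
      for (rep_name in groups[[g]]) {
        hit <- library$reporter == rep_name & library$state == st[[g]]
        if (!any(hit)) {
          stop("library has no state '", st[[g]], "' for reporter ", rep_name,
               call. = FALSE)
        }
      }
    }
  }
  set.seed(as.integer(seed))
  base_HN <- runif(n_residues, 7.2, 9.3)
  base_N <- runif(n_residues, 105, 132)
  reporter_res <- unique(library$residue_number[!is.na(library$delta_HN_ppm)])
  tables <- list()
  for (sp in names(species_states)) {
    st <- species_states[[sp]]
    hn <- base_HN
    nn <- base_N
    for (g in names(st)) {
      for (rep_name in groups[[g]]) {
        row <- library[library$reporter == rep_name & library$state == st[[g]], ][1, ]
        if (row$residue_number <= n_residues && !is.na(row$delta_HN_ppm)) {
          hn[row$residue_number] <- row$delta_HN_ppm
          nn[row$residue_number] <- row$delta_N_ppm
        }
      }
    }
    if (noise_sigma_ppm > 0) {
      hn <- hn + rnorm(n_residues, sd = noise_sigma_ppm)
      nn <- nn + rnorm(n_residues, sd = noise_sigma_ppm / CSP_N_WEIGHT)
    }
    cb <- rep(NA_real_, n_residues)
    if ("isomer" %in% names(st) && n_residues >= 146L) {
      prow <- library[library$reporter == "P146-CB" & library$state == st[["isomer"]], ]
      if (nrow(prow) == 1L && !is.na(prow$delta_CB_ppm)) {
        cb[146L] <- prow$delta_CB_ppm +
          if (noise_sigma_ppm > 0) rnorm(1, sd = noise_sigma_ppm) else 0
      }
    }
    rec <- data.frame(residue_number = seq_len(n_residues),
                      residue_type = "X", delta_HN = hn, delta_N = nn,
                      delta_CB = cb, stringsAsFactors = FALSE)
    rec$residue_type[reporter_res[reporter_res <= n_residues]] <- "R"
    tables[[sp]] <- suppressWarnings(shift_table(rec, species_label = sp))
  }
  list(tables = tables,
       ground_truth = list(species_states = species_states,
                           noise_sigma_ppm = noise_sigma_ppm,
                           n_residues = n_residues, seed = as.integer(seed)))
}

#' Generate a multi-species intensity table at known populations
#'
#' Per residue and species, `intensity = base(residue) * population_s *
#' exp(eps)` with `eps ~ Normal(0, sigma)` (log-normal multiplicative
#' noise), emulating per-residue peak-intensity quantification of
#' coexisting species.
#'
#' @param populations Named numeric vector of fractions summing to 1.
#' @param n_residues Number of residues (default 60).
#' @param noise_sigma Multiplicative log-normal noise SD (e.g. 0.1 for 10%).
#' @param seed Integer seed.
#' @return List with `table` (an [intensity_table()]) and `ground_truth`.
#' @export
make_intensity_table <- function(populations, n_residues = 60L,
                                 noise_sigma = 0, seed = 1L) {
  if (is.null(names(populations))) {
    names(populations) <- paste0("species", seq_along(populations))
  }
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-9) {
    stop("populations must be non-negative and sum to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  base <- runif(n_residues, 0.5, 2)
  vals <- outer(base, populations)
  if (noise_sigma > 0) {
    vals <- vals * exp(matrix(rnorm(length(vals), sd = noise_sigma),
                              nrow = n_residues))
  }
  df <- data.frame(residue_number = seq_len(n_residues), vals,
                   check.names = FALSE)
  names(df) <- c("residue_number", names(populations))
  list(table = intensity_table(df),
       ground_truth = list(populations = populations,
                           noise_sigma = noise_sigma,
                           n_residues = n_residues, seed = as.integer(seed)))
}
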