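make_records <- function(resno, hn, nn, cb = NA_real_, type = "X") {
  data.frame(residue_number = resno, residue_type = type,
             delta_HN = hn, delta_N = nn, delta_CB = cb,
             stringsAsFactors = FALSE)
}

test_that("shift tables read and write CSV round trip", {
  tab <- shift_table(make_records(c(10L, 11L, 12L), c(8.1, 7.9, 8.4),
                                  c(120.5, 118.2, 125.0)),
                     species_label = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(tab, path)
  tab2 <- read_shift_table(path, species_label = "demo")
  expect_identical(nrow(tab2$records), 3L)
  expect_equal(tab2$records, tab$records)
  expect_error(shift_table(make_records(c(1L, 1L), c(8, 8), c(120, 120))),
               "duplicate residue")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("residue_number,delta_HN_ppm\n1,8.0", bad)
  expect_error(read_shift_table(bad), "required columns")
})

test_that("NMR-STAR ingestion extracts backbone H, N and CB shifts", {
  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_synthetic_demo",
    "save_assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Atom_type",
    "      _Atom_chem_shift.Val",
    "      1 5 ALA H  H  8.21",
    "      2 5 ALA N  N 121.40",
    "      3 5 ALA CB C  18.20",
    "      4 6 ILE H  H  7.00",
    "      5 6 ILE N  N 120.80",
    "      6 7 SER H  H  8.30",
    "      7 7 SER N  N 118.00",
    "      8 7 SER CB C  63.50",
    "      9 8 GLY H  H  8.05",
    "     10 8 GLY N  N 109.20",
    "     11 9 ASP H  H  8.44",
    "     12 9 ASP N  N 119.90",
    "   stop_",
    "save_"), star)
  tab <- read_shift_table(star, format = "nmrstar")
  expect_identical(nrow(tab$records), 5L)
  expect_identical(tab$records$residue_type, c("A", "I", "S", "G", "D"))
  expect_equal(tab$records$delta_CB[1], 18.2)
  expect_true(is.na(tab$records$delta_CB[2]))
  expect_equal(tab$records$delta_HN[2], 7.00)
})

test_that("weighted CSP follows the 0.13-weighted amide formula exactly", {
  x <- shift_table(make_records(1:3, c(8.0, 8.5, 7.5), c(120, 125, 115)), "X")
  expect_true(all(weighted_csp(x, x)$delta_delta == 0))

  y_h <- shift_table(make_records(1:3, c(9.0, 8.5, 7.5), c(120, 125, 115)), "Y")
  expect_equal(weighted_csp(x, y_h)$delta_delta, c(1.0, 0, 0))

  y_n <- shift_table(make_records(1:3, c(8.0, 8.5, 7.5), c(130, 125, 115)), "Y")
  expect_equal(weighted_csp(x, y_n)$delta_delta, c(1.3, 0, 0))

  z <- shift_table(make_records(50:52, c(8, 8, 8), c(120, 120, 120)), "Z")
  expect_error(weighted_csp(x, z), "no shared residues")
})

test_that("CSP is symmetric and invariant to a common referencing offset", {
  set.seed(77)
  rec <- make_records(1:40, runif(40, 6.5, 10), runif(40, 105, 135))
  a <- shift_table(rec, "A")
  rec_b <- rec
  rec_b$delta_HN <- rec_b$delta_HN + rnorm(40, sd = 0.1)
  rec_b$delta_N <- rec_b$delta_N + rnorm(40, sd = 0.8)
  b <- shift_table(rec_b, "B")
  expect_equal(weighted_csp(a, b)$delta_delta, weighted_csp(b, a)$delta_delta)
  off <- function(tb, dh, dn) {
    tb$records$delta_HN <- tb$records$delta_HN + dh
    tb$records$delta_N <- tb$records$delta_N + dn
    tb
  }
  expect_equal(weighted_csp(off(a, 0.3, -1.2), off(b, 0.3, -1.2))$delta_delta,
               weighted_csp(a, b)$delta_delta, tolerance = 1e-12)
  # residues absent from one table are absent from the profile, not zero
  expect_identical(weighted_csp(a, shift_table(rec[1:10, ], "B10"))$residue_number,
                   1:10)
})

test_that("library cluster points self-classify at zero distance", {
  lib <- synthetic_reporter_library()
  gen <- make_species_shift_tables(
    lib, list(sp = c(isomer = "cis", closure = "open", mgt = "MgT_free")),
    noise_sigma_ppm = 0, seed = 2L)
  tab <- gen$tables$sp
  iso <- classify_isomer_state(tab, lib)
  expect_identical(iso$state, "cis")
  expect_true(all(iso$evidence$distance < 1e-12))
  clo <- classify_closure_state(tab, lib)
  expect_identical(clo$state, "open")
  expect_true(all(clo$evidence$distance < 1e-12))
})

test_that("noisy reporter draws classify to the generating state", {
  lib <- synthetic_reporter_library()
  hits_iso <- 0; hits_clo <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    gen <- make_species_shift_tables(
      lib, list(sp = c(isomer = "trans", closure = "NAC_III", mgt = "MgT_free")),
      noise_sigma_ppm = 0.02, seed = s)
    tab <- gen$tables$sp
    hits_iso <- hits_iso + (classify_isomer_state(tab, lib)$state == "trans")
    hits_clo <- hits_clo + (classify_closure_state(tab, lib)$state == "NAC_III")
  }
  expect_gte(hits_iso / n_rep, 0.99)
  expect_gte(hits_clo / n_rep, 0.99)
})

test_that("disagreeing reporters yield an ambiguous call", {
  lib <- synthetic_reporter_library()
  a143 <- lib[lib$reporter == "A143" & lib$state == "cis", ]
  d180 <- lib[lib$reporter == "D180" & lib$state == "trans", ]
  tab <- shift_table(make_records(c(143L, 180L),
                                  c(a143$delta_HN_ppm, d180$delta_HN_ppm),
                                  c(a143$delta_N_ppm, d180$delta_N_ppm)))
  expect_identical(classify_isomer_state(tab, lib)$state, "ambiguous")
  no_rep <- shift_table(make_records(1:4, rep(8, 4), rep(120, 4)))
  expect_error(classify_isomer_state(no_rep, lib), "reporters")
})

test_that("the I84 amide proton separates NAC III from its twisted variant", {
  lib <- read_reporter_library()  # shipped, literature-printed values only
  t_nac3 <- shift_table(make_records(84L, 7.00, 120.8))
  t_nac3t <- shift_table(make_records(84L, 7.17, 121.6))
  expect_identical(classify_closure_state(t_nac3, lib)$state, "NAC_III")
  expect_identical(classify_closure_state(t_nac3t, lib)$state, "NAC_III_t")
})

test_that("proline CB shifts classify cis/trans with a midband", {
  expect_identical(classify_proline_isomer(35.0), "cis")
  expect_identical(classify_proline_isomer(32.0), "trans")
  expect_identical(classify_proline_isomer(33.5), "ambiguous")
  expect_error(classify_proline_isomer(NA_real_), "finite")
})

test_that("MgT occupancy is read from the A115 upfield displacement", {
  ref <- shift_table(make_records(c(100L, 115L), c(8.2, 8.5), c(119, 124)), "ref")
  bound <- shift_table(make_records(c(100L, 115L), c(8.2, 6.9), c(119, 124.3)), "b")
  got <- detect_mgt(bound, ref)
  expect_identical(got$state, "MgT_bound")
  expect_equal(got$displacement, 1.6)
  expect_identical(detect_mgt(ref, ref)$state, "MgT_free")
  no115 <- shift_table(make_records(100L, 8.2, 119), "n")
  expect_identical(detect_mgt(no115, ref)$state, "indeterminate")
})

test_that("correlation matching ranks the generating species first", {
  set.seed(88)
  lib <- synthetic_reporter_library()
  states <- list(
    trans_mgt = c(isomer = "trans", closure = "NAC_I", mgt = "MgT_bound"),
    cis_free = c(isomer = "cis", closure = "NAC_III", mgt = "MgT_free"))
  gen <- make_species_shift_tables(lib, states, noise_sigma_ppm = 0, seed = 9L)

  self <- correlation_match(gen$tables$trans_mgt, gen$tables)
  expect_identical(self$candidate[1], "trans_mgt")
  expect_equal(self$r_H[1], 1)
  expect_equal(self$r_N[1], 1)

  # query = candidate plus tiny noise: ranking preserved, r > 0.999
  noisy <- gen$tables$trans_mgt
  noisy$records$delta_HN <- noisy$records$delta_HN + rnorm(221, sd = 0.005)
  noisy$records$delta_N <- noisy$records$delta_N + rnorm(221, sd = 0.005 / 0.13)
  ranked <- correlation_match(noisy, gen$tables)
  expect_identical(ranked$candidate[1], "trans_mgt")
  expect_gt(min(ranked$r_H[1], ranked$r_N[1]), 0.999)
  expect_lt(ranked$p[2], 0.05)  # runner-up correlation significantly lower

  # anti-correlated candidate sorts last with negative r
  anti <- gen$tables$trans_mgt
  anti$records$delta_HN <- max(anti$records$delta_HN) +
    min(anti$records$delta_HN) - anti$records$delta_HN
  anti$records$delta_N <- max(anti$records$delta_N) +
    min(anti$records$delta_N) - anti$records$delta_N
  anti$species_label <- "anti"
  ranked2 <- correlation_match(noisy, c(gen$tables, list(anti = anti)))
  expect_identical(ranked2$candidate[3], "anti")
  expect_lt(ranked2$r_min[3], 0)

  expect_error(correlation_match(shift_table(make_records(1:4, rep(8, 4),
                                                          rep(120, 4))),
                                 list(z = shift_table(make_records(
                                   300:303, rep(8, 4), rep(120, 4))))),
               "shares at least")
})

test_that("the Fisher z-test matches its closed form", {
  eq <- fisher_z_test(0.8, 30, 0.8, 50)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)

  # independent hand computation of the z statistic
  z_hand <- (0.5 * log((1 + 0.9) / (1 - 0.9)) -
               0.5 * log((1 + 0.5) / (1 - 0.5))) / sqrt(1 / 47 + 1 / 47)
  got <- fisher_z_test(0.9, 50, 0.5, 50)
  expect_equal(got$z, z_hand, tolerance = 1e-12)

  # p agrees with a numerically integrated normal tail
  tail_num <- 2 * integrate(dnorm, lower = abs(z_hand), upper = Inf,
                            rel.tol = 1e-13)$value
  expect_equal(got$p, tail_num, tolerance = 1e-10)

  expect_lt(fisher_z_test(0.9998, 77, 0.95, 77)$p, 0.05)
  expect_error(fisher_z_test(1, 10, 0.5, 10), "infinite")
  expect_error(fisher_z_test(0.5, 3, 0.5, 10), "exceed 3")
})
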