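test_that("canonicalisation centres the cap and aligns its principal axes", {
  gen <- make_two_domain_structure(seed = 3L)
  canon <- canonicalize_reference(gen$reference, gen$domains)
  cap <- select_domain_coords(canon, gen$domains, "cap", "ca_only")
  pa <- principal_axes(cap$xyz, orient = -colMeans(
    select_domain_coords(canon, gen$domains, "core", "ca_only")$xyz))
  expect_lt(max(abs(colMeans(cap$xyz))), 1e-9)
  expect_lt(max(abs(pa$axes - diag(3))), 1e-9)
  # idempotence: the generator's reference is already canonical
  expect_lt(max(abs(as.matrix(canon$atoms[, c("x", "y", "z")]) -
                      as.matrix(gen$reference$atoms[, c("x", "y", "z")]))), 1e-9)
})

test_that("canonical form does not depend on the input pose", {
  gen <- make_two_domain_structure(seed = 4L)
  set.seed(14)
  moved <- transform_structure(gen$reference,
                               rigid_transform(random_rotation(), c(30, -12, 8)))
  canon_a <- canonicalize_reference(gen$reference, gen$domains)
  canon_b <- canonicalize_reference(moved, gen$domains)
  dmax <- max(abs(as.matrix(canon_a$atoms[, c("x", "y", "z")]) -
                    as.matrix(canon_b$atoms[, c("x", "y", "z")])))
  expect_lt(dmax, 1e-6)
})

test_that("a rigid copy of the reference shows no interdomain motion", {
  gen <- make_two_domain_structure(seed = 5L)
  set.seed(15)
  copy <- transform_structure(gen$reference,
                              rigid_transform(random_rotation(), c(4, 4, -9)))
  copy$identifier <- "copy"
  res <- motion_profile(copy, gen$reference, gen$domains)
  expect_lt(max(abs(c(res$pitch, res$roll, res$yaw, res$hinge_angle))), 1e-6)
  expect_lt(res$rmsd_to_reference_nonH, 1e-6)
})

test_that("applied Euler angles are recovered over the grid", {
  # noise-free recovery is exact; a sparse sub-grid keeps this test quick and
  # the full grid lives in the acceptance suite
  for (p in c(5, 35)) for (r in c(-10, 10)) for (y in c(-10, 0, 10)) {
    gen <- make_two_domain_structure(angles = euler_angles(p, r, y))
    res <- motion_profile(gen$model, gen$reference, gen$domains)
    expect_lt(max(abs(c(res$pitch - p, res$roll - r, res$yaw - y))), 1e-6)
  }
})

test_that("motion angles are invariant under a global pose change", {
  gen <- make_two_domain_structure(angles = euler_angles(25, -10, 10), seed = 6L)
  base <- motion_profile(gen$model, gen$reference, gen$domains)
  set.seed(16)
  for (i in 1:3) {
    moved <- transform_structure(gen$model,
                                 rigid_transform(random_rotation(),
                                                 runif(3, -20, 20)))
    res <- motion_profile(moved, gen$reference, gen$domains)
    expect_lt(max(abs(c(res$pitch - base$pitch, res$roll - base$roll,
                        res$yaw - base$yaw))), 1e-6)
  }
})

test_that("swapping reference and structure flips the rotation, not its size", {
  gen <- make_two_domain_structure(angles = euler_angles(20, 8, -6))
  fwd <- interdomain_transform(gen$model, gen$reference, gen$domains)
  rev <- interdomain_transform(gen$reference, gen$model, gen$domains)
  expect_equal(rotation_angle(fwd$rotation), rotation_angle(rev$rotation),
               tolerance = 1e-6)
  expect_lt(max(abs(fwd$rotation %*% rev$rotation - diag(3))), 1e-6)
})

test_that("conformer classification picks the nearest labelled centroid", {
  cen <- data.frame(label = c("open", "NAC_I", "NAC_III", "closed"),
                    pitch = c(-30, -9, -2, 0), roll = c(2, -1, 1, 0),
                    yaw = c(-4, 2, 1, 0))
  hit <- classify_conformer(list(pitch = -9, roll = -1, yaw = 2), cen)
  expect_identical(hit$label, "NAC_I")
  expect_identical(hit$distance, 0)

  far <- classify_conformer(list(pitch = 60, roll = 0, yaw = 0), cen, cutoff = 8)
  expect_identical(far$label, "unassigned")

  tie_cen <- data.frame(label = c("b_state", "a_state"),
                        pitch = c(-5, 5), roll = 0, yaw = 0)
  expect_message(tie <- classify_conformer(list(pitch = 0, roll = 0, yaw = 0),
                                           tie_cen, cutoff = 10), "tie")
  expect_identical(tie$label, "b_state")  # centroid row order breaks ties
  expect_error(classify_conformer(list(pitch = 0, roll = 0, yaw = 0),
                                  cen[0, ]), "empty centroid")
})

test_that("noisy draws around known centroids classify correctly", {
  cen <- data.frame(label = c("open", "NAC_I", "NAC_III", "closed"),
                    pitch = c(-35, -26, -9, 0), roll = c(3, 1, -2, 0),
                    yaw = c(-5, 3, 1, 0))
  set.seed(206)
  n_draw <- 200
  truth <- sample(cen$label, n_draw, replace = TRUE)
  correct <- 0
  for (i in seq_len(n_draw)) {
    c0 <- cen[cen$label == truth[i], ]
    got <- classify_conformer(list(pitch = c0$pitch + rnorm(1, sd = 2),
                                   roll = c0$roll + rnorm(1, sd = 2),
                                   yaw = c0$yaw + rnorm(1, sd = 2)),
                              cen, cutoff = 8)
    correct <- correct + (got$label == truth[i])
  }
  expect_gte(correct / n_draw, 0.95)
})

test_that("batch landscape is robust to failures and duplicate ids", {
  gen <- make_two_domain_structure(angles = euler_angles(15, 5, -5))
  empty <- batch_landscape(list(), gen$reference, gen$domains)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("structure_id", "pitch", "hinge_angle", "error") %in%
                    names(empty)))

  broken <- toy_model(300:340, id = "broken")  # shares no residues
  dup <- gen$model
  out <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(
    tab <- batch_landscape(list(gen$model, dup, broken), gen$reference,
                           gen$domains, out = out),
    "duplicate structure id")
  expect_identical(nrow(tab), 3L)
  expect_identical(sum(!is.na(tab$error)), 1L)
  expect_equal(tab$pitch[1], 15, tolerance = 1e-6)
  expect_equal(tab$pitch[2], 15, tolerance = 1e-6)
  expect_identical(anyDuplicated(tab$structure_id), 0L)
  ondisk <- read.delim(out)
  expect_identical(nrow(ondisk), 3L)
})

test_that("centroids built from labelled results feed classification", {
  gens <- list(open = euler_angles(-30, 2, -3), NAC_I = euler_angles(-9, 0, 2),
               closed = euler_angles(0, 0, 0))
  rows <- lapply(names(gens), function(lb) {
    g <- make_two_domain_structure(angles = gens[[lb]])
    r <- motion_profile(g$model, g$reference, g$domains)
    r$label <- lb
    as.data.frame(r)
  })
  cen <- conformer_centroids(do.call(rbind, rows))
  g <- make_two_domain_structure(angles = euler_angles(-9, 0, 2))
  res <- motion_profile(g$model, g$reference, g$domains, centroids = cen)
  expect_identical(res$conformer_class, "NAC_I")
})
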