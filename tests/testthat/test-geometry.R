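rigid_transform <- function(coords, seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- runif(3, -20, 20)
  t(apply(coords, 1, function(p) as.vector(R %*% p) + shift))
}

simple_pose <- function() {
  pose_geometry(rbind(
    nalpha = c(0, 0, 3.1),
    halpha = c(2.0, 1.0, 3.5),
    c4p = c(0, 0, 0),
    n_sb = c(1.28, 0, 0),
    c4 = c(2.0, 1.3, 0),
    neps = c(2.5, 1.0, 2.0)))
}

test_that("NAT length is the Euclidean Nalpha-C4' distance", {
  p <- simple_pose()
  expect_equal(nat_length(p), 3.1)
  set.seed(41)
  for (i in 1:10) {
    co <- matrix(rnorm(18, sd = 4), 6, 3,
                 dimnames = list(c("nalpha", "halpha", "c4p", "n_sb",
                                   "c4", "neps"), NULL))
    d <- as.matrix(dist(co)); diag(d) <- Inf
    if (any(d <= 0.11)) next
    pp <- pose_geometry(co)
    brute <- sqrt(sum((co["nalpha", ] - co["c4p", ])^2))
    expect_equal(nat_length(pp), brute, tolerance = 1e-9)
  }
  # coincident atoms are rejected by the container
  bad <- simple_pose()$coords
  bad["halpha", ] <- bad["neps", ] + 0.01
  expect_error(pose_geometry(bad), "closer than 0.1")
})

test_that("Buergi-Dunitz angle handles canonical fixtures", {
  co <- simple_pose()$coords
  co["nalpha", ] <- c(-3, 0, 0)       # collinear, opposite side of N_sb
  co["halpha", ] <- c(-3, 1.5, 0.5)
  expect_equal(burgi_dunitz(pose_geometry(co)), 180)
  co["nalpha", ] <- c(0, 0, 3.1)      # perpendicular attack
  expect_equal(burgi_dunitz(pose_geometry(co)), 90)
})

test_that("NAT dihedral matches a cross-product torsion oracle", {
  co <- simple_pose()$coords
  co["nalpha", ] <- c(2.0, 1.3, 3.0)  # same side as c4: near-cis
  p <- pose_geometry(co)
  # independent Newman-projection oracle: project onto the plane normal
  # to the C4'-N_sb axis and take the angle between the projections
  newman <- function(co) {
    axis <- co["n_sb", ] - co["c4p", ]; axis <- axis / sqrt(sum(axis^2))
    proj <- function(v) v - sum(v * axis) * axis
    a <- proj(co["nalpha", ] - co["c4p", ])
    b <- proj(co["c4", ] - co["n_sb", ])
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }
  expect_equal(nat_dihedral(p), newman(co), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:15) {
    co2 <- co
    co2["nalpha", ] <- co["c4p", ] + rnorm(3, sd = 2)
    d <- as.matrix(dist(co2)); diag(d) <- Inf
    if (any(d <= 0.11)) next
    p2 <- pose_geometry(co2)
    expect_equal(nat_dihedral(p2), newman(co2), tolerance = 1e-9)
  }
  # collinear triple is an error
  co3 <- simple_pose()$coords
  co3["nalpha", ] <- co3["c4p", ] + 2 * (co3["c4p", ] - co3["n_sb", ])
  expect_error(nat_dihedral(pose_geometry(co3)), "collinear")
})

test_that("alpha-proton accessibility measures distance and face", {
  co <- simple_pose()$coords
  # plane through nalpha, c4p, n_sb is z = 0 here (all three at z = 0)?
  co["nalpha", ] <- c(0.5, 2.0, 0)
  co["halpha", ] <- c(2.5, 1.0, 1.0)   # 1 A above the plane
  co["neps", ] <- c(2.5, 4.0, 1.0)     # same face, 3 A away
  co["c4", ] <- c(2.0, 1.3, -1.0)
  acc <- halpha_accessibility(pose_geometry(co))
  expect_equal(acc$d_Halpha_Neps, 3.0)
  expect_true(acc$same_face)
  co["halpha", ] <- c(2.5, 1.0, -1.0)  # below the plane
  acc2 <- halpha_accessibility(pose_geometry(co))
  expect_false(acc2$same_face)
  # mirror reflection flips the face call but preserves the distance
  m <- co; m[, 3] <- -m[, 3]
  acc3 <- halpha_accessibility(pose_geometry(m))
  expect_equal(acc3$d_Halpha_Neps, acc2$d_Halpha_Neps)
  expect_identical(acc3$same_face, acc2$same_face)
  full_mirror_of_same_face <- simple_pose()$coords
  accA <- halpha_accessibility(pose_geometry(full_mirror_of_same_face))
  fm <- full_mirror_of_same_face; fm[, 1] <- -fm[, 1]
  accB <- halpha_accessibility(pose_geometry(fm))
  expect_identical(accA$same_face, accB$same_face)
  expect_equal(accA$d_Halpha_Neps, accB$d_Halpha_Neps)
})

test_that("all metrics are invariant under rigid-body transforms", {
  fx <- generate_pose(3.1, 105, 90, 3.0, TRUE, seed = 5)
  base <- nat_report(fx$pose)
  for (s in 1:5) {
    moved <- pose_geometry(rigid_transform(fx$pose$coords, seed = s))
    r <- nat_report(moved)
    expect_equal(r$d_NAT, base$d_NAT, tolerance = 1e-9)
    expect_equal(r$theta_BD, base$theta_BD, tolerance = 1e-9)
    expect_equal(r$theta_DH, base$theta_DH, tolerance = 1e-9)
    expect_equal(r$d_Halpha_Neps, base$d_Halpha_Neps, tolerance = 1e-9)
    expect_identical(r$halpha_same_face, base$halpha_same_face)
  }
})

test_that("distances scale linearly and angles are scale invariant", {
  fx <- generate_pose(3.1, 100, 80, 3.0, TRUE, seed = 6)
  scaled <- pose_geometry(fx$pose$coords * 2)
  expect_equal(nat_length(scaled), 2 * nat_length(fx$pose))
  expect_equal(burgi_dunitz(scaled), burgi_dunitz(fx$pose),
               tolerance = 1e-9)
  expect_equal(nat_dihedral(scaled), nat_dihedral(fx$pose),
               tolerance = 1e-9)
})

test_that("classification applies every enabled criterion", {
  productive <- list(d_NAT = 3.1, theta_BD = 91, theta_DH = 78,
                     d_Halpha_Neps = 3.0, halpha_same_face = TRUE)
  expect_equal(classify_pose(productive)$verdict, "productive")
  # wrong-face alpha proton is decisive even with fine lengths/angles
  wrong_face <- within(productive, halpha_same_face <- FALSE)
  cls <- classify_pose(wrong_face)
  expect_equal(cls$verdict, "nonproductive")
  expect_match(cls$reasons, "points away", all = FALSE)
  # disabling every criterion makes any pose productive
  off <- nat_thresholds(d_nat_max = NA, theta_bd_tol = NA,
                        theta_dh_tol = NA, d_halpha_neps_max = NA,
                        require_same_face = FALSE)
  far <- list(d_NAT = 9, theta_BD = 10, theta_DH = 170,
              d_Halpha_Neps = 12, halpha_same_face = FALSE)
  expect_equal(classify_pose(far, off)$verdict, "productive")
})

test_that("tightening thresholds never turns nonproductive into productive", {
  set.seed(43)
  for (i in 1:30) {
    metrics <- list(d_NAT = runif(1, 2, 6), theta_BD = runif(1, 0, 180),
                    theta_DH = runif(1, 0, 180),
                    d_Halpha_Neps = runif(1, 1, 8),
                    halpha_same_face = runif(1) > 0.5)
    loose <- nat_thresholds()
    tight <- nat_thresholds(d_nat_max = loose$d_nat_max - runif(1, 0, 1),
                            theta_bd_tol = loose$theta_bd_tol - runif(1, 0, 20),
                            theta_dh_tol = loose$theta_dh_tol - runif(1, 0, 20),
                            d_halpha_neps_max =
                              loose$d_halpha_neps_max - runif(1, 0, 2))
    v_loose <- classify_pose(metrics, loose)$verdict
    v_tight <- classify_pose(metrics, tight)$verdict
    if (v_loose == "nonproductive") expect_equal(v_tight, "nonproductive")
  }
})

test_that("PDB poses round-trip through file within format precision", {
  tmp <- tempfile(fileext = ".pdb")
  fx <- generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 7, path = tmp)
  pose <- read_pose(tmp, fx$map)
  expect_lt(max(abs(pose$coords - fx$pose$coords)), 1e-3)
  r <- nat_report(pose)
  expect_equal(r$d_NAT, 3.1, tolerance = 2e-3)
  expect_equal(r$theta_BD, 91, tolerance = 0.1)
  expect_equal(r$theta_DH, 78, tolerance = 0.1)
  expect_equal(r$d_Halpha_Neps, 3.0, tolerance = 2e-3)
  unlink(tmp)
})

test_that("pose reading errors name the failing selector", {
  tmp <- tempfile(fileext = ".pdb")
  fx <- generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 8, path = tmp)
  bad_map <- fx$map
  class(bad_map) <- NULL
  bad_map$neps$resno <- 999L
  bad_map <- do.call(atom_map, bad_map)
  expect_error(read_pose(tmp, bad_map), "neps.*matches no atom")
  # missing alpha proton gets the explicit hydrogens-required error
  lines <- fx$pdb_lines
  writeLines(lines[!grepl(" HA ", lines)], tmp)
  expect_error(read_pose(tmp, fx$map), "hydrogens are required")
  # duplicated atom record makes the selector ambiguous (the parser also
  # warns about the duplicated element number)
  writeLines(c(lines[-length(lines)], lines[1], "END"), tmp)
  suppressWarnings(expect_error(read_pose(tmp, fx$map), "ambiguous"))
  unlink(tmp)
})
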