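# RMSD fields, localisation spaces, isosurface angles, exports.

single_fit_for <- function(study, site = 1, metal = "Tb") {
  lab <- sprintf("site%d:synthetic:%s", site, metal)
  pcs_fit(study$datasets[lab], study$structure, site_residue = 1000L + site)
}

test_that("the RMSD field equals a direct evaluation and dips at the source", {
  study <- noise_free_study(21)
  fit <- single_fit_for(study, 1)
  lab <- fit$labels
  x_star <- as.numeric(study$targets[1, c("x", "y", "z")])
  tp <- stats::setNames(pcs_forward(study$tensors[[lab]], x_star), lab)
  g <- grid_spec(study$structure, spacing = 1, margin = 8)
  f <- rmsd_field(fit, tp, g)
  expect_s3_class(f, "scalar_field")
  expect_true(all(f$values >= 0))
  # direct-evaluation oracle at an arbitrary grid node
  idx <- c(4, 7, 9)
  node <- f$origin + (idx - 1) * f$spacing
  manual <- sqrt(mean((tp - pcs_forward(fit$tensors[[lab]], node))^2))
  expect_equal(f$values[idx[1], idx[2], idx[3]], manual, tolerance = 1e-10)
  # the field at the generating point is (near) zero for noise-free data
  expect_lt(pcsloc:::rmsd_at(fit, tp, x_star), 1e-6)

  # duplicating a dataset leaves the field unchanged
  fit2 <- fit
  fit2$tensors <- c(fit$tensors, fit$tensors)
  names(fit2$tensors) <- c(lab, "dup")
  fit2$labels <- names(fit2$tensors)
  tp2 <- stats::setNames(c(tp, tp), fit2$labels)
  f2 <- rmsd_field(fit2, tp2, g)
  expect_equal(f2$values, f$values, tolerance = 1e-12)

  expect_error(rmsd_field(fit, c(nosuch = 1), g), "nosuch")
})

test_that("extract_space handles empty, full, and containing cutoffs", {
  study <- noise_free_study(22)
  fit <- single_fit_for(study, 1)
  lab <- fit$labels
  x_star <- as.numeric(study$targets[1, c("x", "y", "z")])
  tp <- stats::setNames(pcs_forward(study$tensors[[lab]], x_star), lab)
  g <- grid_spec(study$structure, spacing = 1.5, margin = 6)
  f <- rmsd_field(fit, tp, g)
  expect_warning(empty <- extract_space(f, min(f$values) * 0.5), "empty")
  expect_equal(empty$n, 0L)
  all_nodes <- extract_space(f, max(f$values) + 1)
  expect_equal(all_nodes$n, prod(f$shape))
  expect_true(all(all_nodes$values <= all_nodes$cutoff))

  # noisy case: generating position lies in the space cut at 2 * sigma
  sigma <- 0.01
  cfg <- generator_config(seed = 23, noise_sigma = sigma)
  noisy <- simulate_study(cfg)
  fitn <- single_fit_for(noisy, 1)
  tpn <- stats::setNames(noisy$target_pcs["HZ2", fitn$labels], fitn$labels)
  xs <- as.numeric(noisy$targets[1, c("x", "y", "z")])
  expect_lte(pcsloc:::rmsd_at(fitn, tpn, xs), 2 * sigma)
})

test_that("space metrics report centroid distance and overlap", {
  mk <- function(pts, vals = rep(0.1, nrow(pts)), cutoff = 1)
    structure(list(cutoff = cutoff, points = pts, values = vals,
                   centroid = colMeans(pts),
                   extent = if (nrow(pts) > 1) max(stats::dist(pts)) else 0,
                   n = nrow(pts)), class = "localisation_space")
  a <- mk(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(space_metrics(a, a),
               list(centroid_distance = 0, overlap_fraction = 1))
  b <- mk(rbind(c(2.9, 0, 0)))
  a1 <- mk(rbind(c(0, 0, 0)))
  m <- space_metrics(a1, b)
  expect_equal(m$centroid_distance, 2.9)
  expect_equal(m$overlap_fraction, 0)
  expect_error(space_metrics(a, structure(list(n = 0L),
                                          class = "localisation_space")),
               "empty")
})

test_that("isosurface angles follow the acute-gradient definition", {
  set.seed(41)
  tA <- random_tensor(c(0, 0, 0))
  p <- c(4, 5, -3)
  tB <- chi_tensor(tA$position, 2 * tA$components)
  expect_equal(isosurface_angle(tA, tB, p), 0, tolerance = 1e-8)
  tC <- chi_tensor(tA$position, -tA$components)
  expect_equal(isosurface_angle(tA, tC, p), 0, tolerance = 1e-8)

  # finite-difference oracle for two separated axial tensors
  t1 <- chi_from_principal(c(-6, 0, 0), dax = 15)
  R <- pcsloc:::euler_to_matrix(0, pi / 2, 0)   # principal z along x
  t2 <- chi_from_principal(c(6, 0, 0), dax = 15, R = R)
  pt <- c(0, 4, 2)
  fd_grad <- function(tt) vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- 1e-5
    (pcs_forward(tt, pt + e) - pcs_forward(tt, pt - e)) / 2e-5
  }, 0)
  g1 <- fd_grad(t1); g2 <- fd_grad(t2)
  oracle <- pcsloc:::deg(acos(abs(sum(g1 * g2)) /
                                sqrt(sum(g1^2) * sum(g2^2))))
  expect_equal(isosurface_angle(t1, t2, pt), oracle, tolerance = 1e-4)
  expect_error(isosurface_angle(
    chi_tensor(c(0, 0, 0), rep(0, 5)), tA, p), "zero")
})

test_that("selection report flags shallow same-site two-metal pairs only", {
  cfg <- generator_config(seed = 31)
  study <- simulate_study(cfg)
  fits <- lapply(1:3, function(s) {
    labs <- grep(paste0("^site", s, ":"), names(study$datasets), value = TRUE)
    pcs_fit(study$datasets[labs], study$structure, site_residue = 1000L + s)
  })
  tp <- study$target_pcs["HZ2", ]
  rep <- dataset_selection_report(fits, tp, grid_spec(study$structure, 1, 10),
                                  threshold = 20)
  same <- rep[rep$same_site_tag, ]
  expect_equal(nrow(same), 3)            # one Tb/Tm pair per site
  expect_true(all(same$angle < 20))      # 5-degree jitter: near-parallel
  expect_true(all(same$flagged))
  diff_site <- rep[!rep$same_site_tag, ]
  expect_false(any(diff_site$flagged))
  # policy keeps the larger-|dax| (Tb-like) member
  excl <- attr(rep, "excluded")
  expect_length(excl, 3)
  expect_true(all(grepl(":Tm$", excl)))

  single <- dataset_selection_report(fits[[1]], tp[fits[[1]]$labels[1]],
                                     grid_spec(study$structure, 1, 10))
  expect_equal(nrow(single), 0)
})

test_that("OpenDX round-trips and pseudo-atom export matches the space", {
  study <- noise_free_study(25)
  fit <- single_fit_for(study, 1)
  lab <- fit$labels
  x_star <- as.numeric(study$targets[1, c("x", "y", "z")])
  tp <- stats::setNames(pcs_forward(study$tensors[[lab]], x_star), lab)
  f <- rmsd_field(fit, tp, grid_spec(study$structure, spacing = 2, margin = 4))
  dx <- withr::local_tempfile(fileext = ".dx")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  sp <- extract_space(f, stats::quantile(f$values, 0.1))
  export_space(sp, f, dx_path = dx, pdb_path = pdb)
  back <- read_dx(dx)
  expect_equal(back$shape, f$shape)
  expect_equal(back$origin, f$origin, tolerance = 1e-5)
  expect_equal(back$values, f$values, tolerance = 1e-5)
  lines <- readLines(pdb)
  atoms <- grep("^HETATM", lines, value = TRUE)
  expect_length(atoms, sp$n)
  b <- as.numeric(substr(atoms, 61, 66))
  expect_true(all(b <= sp$cutoff + 0.01))
})

test_that("field minimum is equivariant under a rigid rotation of the problem", {
  study <- noise_free_study(26)
  fit <- single_fit_for(study, 1)
  fits <- lapply(1:3, function(s) single_fit_for(study, s))
  tp <- vapply(fits, function(f)
    pcs_forward(study$tensors[[f$labels]],
                as.numeric(study$targets[1, c("x", "y", "z")])), 0)
  names(tp) <- vapply(fits, function(f) f$labels, "")
  loc0 <- localise(fits, tp, study$structure, spacing = 1, margin = 8,
                   cutoff = 1)
  m0 <- loc0$minimum

  set.seed(4)
  R <- pcsloc:::random_rotation()
  rot_fits <- lapply(fits, function(f) {
    t <- f$tensors[[1]]
    M <- R %*% as.matrix(t) %*% t(R)
    f$tensors[[1]] <- pcsloc:::chi_from_matrix(drop(R %*% t$position), M)
    f
  })
  rot_struct <- study$structure
  xyz <- as.matrix(study$structure[, c("x", "y", "z")]) %*% t(R)
  rot_struct$x <- xyz[, 1]; rot_struct$y <- xyz[, 2]; rot_struct$z <- xyz[, 3]
  loc1 <- localise(rot_fits, tp, rot_struct, spacing = 1, margin = 8,
                   cutoff = 1)
  m1 <- loc1$minimum
  # the field itself is equivariant: f_rot(R x) = f(x)
  set.seed(6)
  X <- matrix(stats::rnorm(30, sd = 8), 10, 3)
  expect_equal(pcsloc:::rmsd_at(rot_fits, tp, X %*% t(R)),
               pcsloc:::rmsd_at(fits, tp, X), tolerance = 1e-8)
  # each frame's minimum is a global minimiser of the other (the exact
  # zero set can contain several roots, so positions need not coincide)
  expect_equal(pcsloc:::rmsd_at(fits, tp, drop(t(R) %*% m1$position)),
               m1$value, tolerance = 1e-6)
  expect_equal(m1$value, m0$value, tolerance = 0.05)
})

test_that("ensemble averaging does not undercut the full-fit minimum by more than the noise", {
  cfg <- generator_config(seed = 33)
  study <- simulate_study(cfg)
  labs <- grep(":Tb$", names(study$tensors), value = TRUE)
  ens <- lapply(1:3, function(s)
    pcs_bootstrap(study$datasets[paste0("site", s, ":synthetic:Tb")],
                  study$structure, n_members = 8, seed = 5,
                  site_residue = 1000L + s))
  fits <- lapply(1:3, function(s) single_fit_for(study, s))
  tp <- study$target_pcs["HZ2", labs]
  g <- grid_spec(study$structure, spacing = 1.5, margin = 8)
  f_ens <- rmsd_field(ens, tp, g)
  f_full <- rmsd_field(fits, tp, g)
  expect_gte(min(f_ens$values), min(f_full$values) - cfg$noise_sigma)
})
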