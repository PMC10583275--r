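# Linear component solves, common-position fits, Q factors, structure
# ranking, bootstrap ensembles, NPC I/O.

test_that("Q factor matches its defining cases and is scale-consistent", {
  obs <- c(0.5, -1.2, 2.0)
  expect_equal(q_factor(obs, obs), 0)
  expect_equal(q_factor(obs, rep(0, 3)), 1)
  expect_equal(q_factor(obs, 2 * obs), 1)
  calc <- c(0.4, -1.0, 2.2)
  expect_equal(q_factor(obs, calc), q_factor(3 * obs, 3 * calc))
  expect_error(q_factor(c(0, 0), c(1, 1)), "undefined")
})

test_that("linear component fit recovers a known tensor from exact data", {
  set.seed(2)
  truth <- random_tensor(c(1, 2, 3))
  X <- sweep(matrix(stats::rnorm(60, sd = 8), 20, 3), 2, truth$position, "+")
  X <- X[sqrt(rowSums(sweep(X, 2, truth$position)^2)) > 3, , drop = FALSE]
  vals <- pcs_forward(truth, X)
  fit <- fit_components_linear(truth$position, atom_positions = X,
                               values = vals)
  expect_equal(fit$components, truth$components, tolerance = 1e-8)

  expect_error(fit_components_linear(truth$position,
                                     atom_positions = X[1:4, ],
                                     values = vals[1:4]),
               "underdetermined")
  zero <- fit_components_linear(truth$position, atom_positions = X,
                                values = rep(0, nrow(X)))
  expect_equal(unname(zero$components), rep(0, 5), tolerance = 1e-12)
})

test_that("common-position fit recovers position and tensors exactly without noise", {
  study <- noise_free_study(42)
  sites <- attr(study$structure, "sites")
  labs <- grep("^site1:", names(study$datasets), value = TRUE)
  fit <- pcs_fit(study$datasets[labs], study$structure, site_residue = 1001)
  truth_pos <- as.numeric(sites[1, c("metal_x", "metal_y", "metal_z")])
  expect_lt(pcsloc:::vnorm(fit$position - truth_pos), 1e-3)
  for (l in labs) {
    rel <- max(abs(fit$tensors[[l]]$components - study$tensors[[l]]$components)) /
      max(abs(study$tensors[[l]]$components))
    expect_lt(rel, 1e-6)
  }
  expect_lt(fit$q_factor, 1e-8)
  expect_true(fit$metal_cb_distance >= 8.2 - 0.5 &&
                fit$metal_cb_distance <= 9.4 + 0.5)

  # single dataset degenerates to a one-tensor fit
  fit1 <- pcs_fit(study$datasets[labs[1]], study$structure,
                  site_residue = 1001)
  expect_length(fit1$tensors, 1)
  expect_lt(pcsloc:::vnorm(fit1$position - truth_pos), 0.2)
})

test_that("optimised position beats the start hint and the grid-search oracle agrees", {
  study <- noise_free_study(5)
  sites <- attr(study$structure, "sites")
  labs <- grep("^site2:", names(study$datasets), value = TRUE)
  fit <- pcs_fit(study$datasets[labs], study$structure, site_residue = 1002)
  cb <- as.numeric(sites[2, c("cb_x", "cb_y", "cb_z")])
  matched <- lapply(study$datasets[labs], pcsloc:::match_dataset,
                    model = study$structure)
  obj <- function(p) pcsloc:::pooled_objective(p, matched, "value")
  expect_lte(fit$objective, obj(cb) + 1e-12)

  # exhaustive 0.5 A grid over a 5 A box centred on the optimum
  g <- expand.grid(x = seq(-2.5, 2.5, 0.5), y = seq(-2.5, 2.5, 0.5),
                   z = seq(-2.5, 2.5, 0.5))
  vals <- apply(sweep(as.matrix(g), 2, fit$position, "+"), 1, obj)
  best <- as.numeric(g[which.min(vals), ]) + fit$position
  expect_lte(pcsloc:::vnorm(best - fit$position), 0.5)
})

test_that("structure ranking prefers the generating structure with stable ties", {
  study <- noise_free_study(8)
  labs <- grep("^site1:", names(study$datasets), value = TRUE)
  # decoy: jitter every amide position
  decoy <- study$structure
  set.seed(99)
  decoy$x <- decoy$x + stats::rnorm(nrow(decoy), sd = 0.6)
  decoy$y <- decoy$y + stats::rnorm(nrow(decoy), sd = 0.6)
  decoy$z <- decoy$z + stats::rnorm(nrow(decoy), sd = 0.6)
  tab <- rank_structures(study$datasets[labs],
                         list(true = study$structure, decoy = decoy),
                         site_residues = c(site1 = 1001))
  expect_equal(tab$structure_label[1], "true")
  expect_true(tab$winner[1])
  expect_lt(tab$Q[1], tab$Q[2])

  tie <- rank_structures(study$datasets[labs],
                         list(a = study$structure, b = study$structure),
                         site_residues = c(site1 = 1001))
  expect_lt(abs(tie$Q[1] - tie$Q[2]), 1e-10)
  expect_equal(tie$structure_label[1], "a")

  # perturbing only atoms that carry no PCS leaves Q unchanged
  loop <- study$structure
  cb_rows <- loop$elety == "CB"
  loop$x[cb_rows] <- loop$x[cb_rows] + 3
  tab2 <- rank_structures(study$datasets[labs],
                          list(ref = study$structure, loop = loop),
                          site_residues = c(site1 = 1001))
  expect_lt(abs(tab2$Q[1] - tab2$Q[2]), 1e-6)
})

test_that("bootstrap ensembles honour the omission contract and are reproducible", {
  cfg <- generator_config(seed = 6)
  study <- simulate_study(cfg)
  labs <- grep("^site1:", names(study$datasets), value = TRUE)
  N <- nrow(study$datasets[[labs[1]]])
  bs <- pcs_bootstrap(study$datasets[labs], study$structure, n_members = 6,
                      omission_fraction = 0.2, seed = 11,
                      site_residue = 1001)
  expect_length(bs$members, 6)
  for (m in bs$members)
    expect_equal(m$n_points, 2 * ceiling(0.8 * N))
  bs2 <- pcs_bootstrap(study$datasets[labs], study$structure, n_members = 6,
                       omission_fraction = 0.2, seed = 11,
                       site_residue = 1001)
  expect_identical(lapply(bs$members, `[[`, "position"),
                   lapply(bs2$members, `[[`, "position"))
  # different seed draws different subsets
  bs3 <- pcs_bootstrap(study$datasets[labs], study$structure, n_members = 6,
                       omission_fraction = 0.2, seed = 12,
                       site_residue = 1001)
  expect_false(identical(lapply(bs$members, `[[`, "position"),
                         lapply(bs3$members, `[[`, "position")))

  clean <- noise_free_study(13)
  labs0 <- grep("^site1:", names(clean$datasets), value = TRUE)
  bs0 <- pcs_bootstrap(clean$datasets[labs0], clean$structure,
                       n_members = 4, seed = 2, site_residue = 1001)
  for (m in bs0$members)
    expect_lt(pcsloc:::vnorm(m$position - bs0$full$position), 1e-6)
})

test_that("NPC tables round-trip and unmatched entries are dropped with a note", {
  study <- noise_free_study(3)
  d <- study$datasets[[1]]
  path <- withr::local_tempfile(fileext = ".npc")
  write_npc(d, path)
  back <- read_npc(path, attr(d, "site"), attr(d, "tag"), attr(d, "metal"))
  expect_equal(back$resno, d$resno)
  expect_equal(back$value, d$value, tolerance = 1e-6)
  expect_equal(attr(back, "label"), attr(d, "label"))

  extra <- rbind(as.data.frame(d),
                 data.frame(resno = 9999L, elety = "H", value = 0.1,
                            error = 0))
  d2 <- pcs_dataset("s", "t", "m", extra)
  expect_message(md <- pcsloc:::match_dataset(d2, study$structure),
                 "dropped 1")
  expect_equal(length(md$values), nrow(d))
})

test_that("dataset construction rejects invalid tables", {
  expect_error(pcs_dataset("s", "t", "m",
                           data.frame(resno = 1, elety = "H", value = 1,
                                      error = -0.1)), "negative")
  expect_error(pcs_dataset("s", "t", "m",
                           data.frame(resno = c(1, 1), elety = c("H", "H"),
                                      value = 1:2)), "duplicate")
  expect_error(pcs_dataset("s", "t", "m",
                           data.frame(resno = integer(), elety = character(),
                                      value = numeric())), "empty")
})
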