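# Synthetic study generator: a compact pseudo-protein of backbone amide
# protons, lanthanoid tag sites on its surface, per-site tensor pairs of
# different magnitude and sign but closely similar orientation (the
# Tb/Tm analogue), an indole-like target proton pair, and noisy,
# incomplete PCS datasets.  Every stage draws from its own substream of
# one root seed, so each artefact is individually reproducible.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a three-site, two-metal lanthanoid tagging study:
#' Tb-like (dax 25, drh 8) and Tm-like (dax -15, drh -5) tensors in
#' 1e-32 m^3 sharing a closely similar orientation per site (5 degrees
#' jitter), 0.01 ppm Gaussian PCS noise, and 20% of the amides
#' unobserved per dataset.
#'
#' @param n_amides number of backbone amide protons (default 60).
#' @param n_sites number of tag sites (default 3).
#' @param metals_per_site 1 (Tb-like only) or 2 (default).
#' @param noise_sigma Gaussian PCS noise, ppm (default 0.01).
#' @param omission_fraction_observed fraction of amides lacking a PCS per
#'   dataset (default 0.2).
#' @param orientation_jitter angle between same-site metal tensors,
#'   degrees (default 5).
#' @param tensor_magnitudes named list of per-metal `c(dax, drh)` in
#'   1e-32 m^3.
#' @param seed integer root seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_amides = 60, n_sites = 3,
                             metals_per_site = 2, noise_sigma = 0.01,
                             omission_fraction_observed = 0.2,
                             orientation_jitter = 5,
                             tensor_magnitudes = list(Tb = c(25, 8),
                                                      Tm = c(-15, -5)),
                             seed = 1) {
  stopifnot(n_amides >= 20, n_sites >= 1, metals_per_site >= 1,
            metals_per_site <= length(tensor_magnitudes),
            noise_sigma >= 0,
            omission_fraction_observed >= 0, omission_fraction_observed < 1)
  for (m in tensor_magnitudes)
    if (abs(m[2]) > (2 / 3) * abs(m[1]) + 1e-12)
      stop("generator_config: |drh| must not exceed (2/3)|dax|")
  structure(list(n_amides = n_amides, n_sites = n_sites,
                 metals_per_site = metals_per_site,
                 noise_sigma = noise_sigma,
                 omission_fraction_observed = omission_fraction_observed,
                 orientation_jitter = orientation_jitter,
                 tensor_magnitudes = tensor_magnitudes, seed = seed),
            class = "generator_config")
}

# unit vectors with guaranteed pairwise angular separation (degrees)
spread_directions <- function(n, min_angle = 60) {
  dirs <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(dirs) < n) {
    v <- unit(stats::rnorm(3))
    ok <- nrow(dirs) == 0 ||
      all(acos(pmin(1, dirs %*% v)) > rad(min_angle))
    if (ok) dirs <- rbind(dirs, v)
    tries <- tries + 1
    if (tries > 10000) stop("could not place spread directions")
  }
  dirs
}

#' Generate a pseudo-protein structure with tag sites
#'
#' Amide protons are packed with a minimum pairwise separation of 3.3
#' Angstrom inside a sphere of radius `(3 * n_amides)^(1/3) * 2`; each
#' tag site gets a CB anchor on the sphere surface (site directions at
#' least 60 degrees apart) and a paramagnetic-centre position drawn
#' uniformly at 8.2-9.4 Angstrom from its CB, pointing outward within a
#' 30-degree cone — the geometry of a cysteine-attached tag.
#'
#' @param config a [generator_config()].
#' @return a [structure_model()] of `H` atoms (residues 1..n) plus one
#'   `CB` per site (residues 1001, 1002, ...), with attribute `"sites"`:
#'   data.frame of site labels, CB residue numbers, CB and true metal
#'   coordinates.
#' @export
generate_structure <- function(config) {
  n <- config$n_amides
  radius <- (3 * n)^(1 / 3) * 2
  with_seed(sub_seed(config$seed, "structure"), {
    pts <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(pts) < n) {
      tries <- tries + 1
      if (tries > 200000)
        stop("amide packing failed; increase the sphere radius or reduce n_amides")
      p <- stats::runif(3, -radius, radius)
      if (vnorm(p) > radius) next
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= 3.3)
        pts <- rbind(pts, p)
    }
    dirs <- spread_directions(config$n_sites, 60)
    sites <- lapply(seq_len(config$n_sites), function(s) {
      cb <- dirs[s, ] * radius
      # outward cone, half-angle 30 degrees
      ax <- unit(stats::rnorm(3))
      metal_dir <- unit(rotation_about(cross_or_any(dirs[s, ], ax),
                                       stats::runif(1, 0, 30)) %*% dirs[s, ])
      metal <- cb + drop(metal_dir) * stats::runif(1, 8.2, 9.4)
      data.frame(site_label = paste0("site", s), resno = 1000L + s,
                 cb_x = cb[1], cb_y = cb[2], cb_z = cb[3],
                 metal_x = metal[1], metal_y = metal[2], metal_z = metal[3],
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, sites)
    atoms <- rbind(
      data.frame(chain = "A", resno = seq_len(n), resid = "GLY",
                 elety = "H", x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 stringsAsFactors = FALSE),
      data.frame(chain = "A", resno = sites$resno, resid = "CYS",
                 elety = "CB", x = sites$cb_x, y = sites$cb_y,
                 z = sites$cb_z, stringsAsFactors = FALSE))
    model <- structure_model(atoms, label = sprintf("synthetic-%d", config$seed))
    attr(model, "sites") <- sites
    model
  })
}

cross_or_any <- function(a, b) {
  v <- cross3(a, b)
  if (vnorm(v) < 1e-8) v <- cross3(a, c(1, 0, 0))
  if (vnorm(v) < 1e-8) v <- cross3(a, c(0, 1, 0))
  v
}

#' Place an indole-like target proton pair
#'
#' Two target nuclei (Hz2- and He1-like) exactly 2.9 Angstrom apart — the
#' separation of the two outer indole-ring protons — placed
#' `surface_offset` Angstrom outside the amide cloud in a random
#' orientation.
#'
#' @param structure output of [generate_structure()].
#' @param surface_offset distance beyond the amide sphere, Angstrom
#'   (default 5).
#' @param seed integer; defaults to a substream of the structure's
#'   generating seed embedded in its label.
#' @return data.frame of two atom records (residue 2001, `HZ2` and
#'   `HE1`).
#' @export
place_indole_pair <- function(structure, surface_offset = 5, seed = NULL) {
  if (is.null(seed)) {
    seed <- as.integer(sub("synthetic-", "", attr(structure, "model_label")))
    if (is.na(seed)) seed <- 0L
  }
  amides <- structure[structure$elety == "H", , drop = FALSE]
  radius <- max(sqrt(rowSums(atom_xyz(amides)^2)))
  with_seed(sub_seed(seed, "indole"), {
    u <- unit(stats::rnorm(3))
    centre <- u * (radius + surface_offset)
    v <- unit(cross_or_any(u, stats::rnorm(3)))
    p1 <- centre + 1.45 * v
    p2 <- centre - 1.45 * v
    data.frame(chain = "A", resno = 2001L, resid = "TRP",
               elety = c("HZ2", "HE1"),
               x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
               z = c(p1[3], p2[3]), stringsAsFactors = FALSE)
  })
}

#' Generate ground-truth tensors for each site and metal
#'
#' Per site, one random base orientation; the first metal (Tb-like, the
#' larger |dax|) uses it directly, the second (Tm-like, opposite sign)
#' uses the base orientation perturbed by `orientation_jitter` degrees
#' about a random axis — tensors of different magnitude and sign but
#' closely similar orientation, as two lanthanoids in the same rigid tag
#' produce.
#'
#' @param config a [generator_config()].
#' @param sites the `"sites"` attribute of [generate_structure()].
#' @return named list of [chi_tensor()], labels `"siteN:synthetic:METAL"`.
#' @export
generate_tensors <- function(config, sites) {
  metals <- names(config$tensor_magnitudes)[seq_len(config$metals_per_site)]
  with_seed(sub_seed(config$seed, "tensors"), {
    out <- list()
    for (s in seq_len(nrow(sites))) {
      base <- random_rotation()
      metal_pos <- as.numeric(sites[s, c("metal_x", "metal_y", "metal_z")])
      for (k in seq_along(metals)) {
        R <- if (k == 1) base else
          rotation_about(unit(stats::rnorm(3)), config$orientation_jitter) %*% base
        mag <- config$tensor_magnitudes[[metals[k]]]
        lab <- paste(sites$site_label[s], "synthetic", metals[k], sep = ":")
        out[[lab]] <- chi_from_principal(metal_pos, mag[1], mag[2], R = R)
      }
    }
    out
  })
}

#' Simulate PCS datasets from ground-truth tensors
#'
#' Back-calculates the PCS of every amide proton from each tensor, adds
#' Gaussian noise, and drops a random `omission_fraction_observed` of the
#' amides per dataset (emulating incomplete resonance assignments). When
#' `dir` is given the datasets are written as NPC files together with a
#' plain-text ground-truth ledger (tensors, metal positions) for recovery
#' tests; no analysis stage reads the ledger.
#'
#' @param structure output of [generate_structure()].
#' @param tensors output of [generate_tensors()].
#' @param config the [generator_config()].
#' @param dir optional output directory.
#' @return list: `datasets` (named list of [pcs_dataset()]), `truth`
#'   (list of tensors), `files` (paths written, or NULL).
#' @export
simulate_pcs <- function(structure, tensors, config, dir = NULL) {
  amides <- structure[structure$elety == "H", , drop = FALSE]
  X <- atom_xyz(amides)
  n <- nrow(amides)
  n_obs <- round((1 - config$omission_fraction_observed) * n)
  datasets <- list()
  for (i in seq_along(tensors)) {
    lab <- names(tensors)[i]
    parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
    vals <- with_seed(sub_seed(config$seed, paste0("pcs:", lab)), {
      delta <- pcs_forward(tensors[[i]], X) +
        stats::rnorm(n, 0, config$noise_sigma)
      keep <- sort(sample.int(n, n_obs))
      data.frame(resno = amides$resno[keep], elety = "H",
                 value = delta[keep], error = config$noise_sigma)
    })
    datasets[[lab]] <- pcs_dataset(parts[1], parts[2], parts[3], vals)
  }
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (lab in names(datasets)) {
      f <- file.path(dir, paste0(gsub(":", "_", lab), ".npc"))
      write_npc(datasets[[lab]], f)
      files <- c(files, f)
    }
    ledger <- file.path(dir, "ground_truth.txt")
    con <- file(ledger, "w")
    writeLines("# ground-truth ledger (not read by any analysis stage)", con)
    for (lab in names(tensors)) {
      t <- tensors[[lab]]
      p <- principal_form(t)
      writeLines(sprintf(
        "%s metal %.6f %.6f %.6f dax %.6f drh %.6f euler_deg %.4f %.4f %.4f",
        lab, t$position[1], t$position[2], t$position[3], p$dax, p$drh,
        deg(p$euler[1]), deg(p$euler[2]), deg(p$euler[3])), con)
    }
    close(con)
    files <- c(files, ledger)
  }
  list(datasets = datasets, truth = tensors, files = files)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: structure, indole target pair, ground-truth
#' tensors, backbone PCS datasets, and noisy target PCSs for both indole
#' nuclei.
#'
#' @param config a [generator_config()].
#' @return list: `structure`, `targets` (the indole pair records),
#'   `tensors` (ground truth), `datasets`, `target_pcs` (2 x datasets
#'   matrix of noisy target PCSs, rows HZ2/HE1), `config`.
#' @export
simulate_study <- function(config = generator_config()) {
  structure <- generate_structure(config)
  targets <- place_indole_pair(structure, seed = config$seed)
  sites <- attr(structure, "sites")
  tensors <- generate_tensors(config, sites)
  sim <- simulate_pcs(structure, tensors, config)
  TX <- atom_xyz(targets)
  target_pcs <- with_seed(sub_seed(config$seed, "target-pcs"), {
    m <- vapply(tensors, function(t) pcs_forward(t, TX), numeric(2)) +
      stats::rnorm(2 * length(tensors), 0, config$noise_sigma)
    matrix(m, nrow = 2, dimnames = list(targets$elety, names(tensors)))
  })
  list(structure = structure, targets = targets, tensors = tensors,
       datasets = sim$datasets, target_pcs = target_pcs, config = config)
}
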