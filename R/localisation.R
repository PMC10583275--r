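# Localisation of target nuclei: map the 3D field of RMS deviations
# between observed target PCSs and the values back-calculated from the
# fitted tensor ensembles, then cut it at a maximal-RMSD boundary.

#' Define a regular 3D grid
#'
#' @param structure a [structure_model()] (or any data.frame with x, y, z)
#'   whose bounding box the grid covers; alternatively give `origin` and
#'   `shape` directly.
#' @param spacing grid spacing, Angstrom (default 1).
#' @param margin padding around the bounding box, Angstrom (default 10).
#' @param origin,shape explicit grid origin (length 3) and node counts
#'   (length 3), overriding `structure`.
#' @return list of class `grid_spec` with `origin`, `spacing`, `shape`.
#' @export
grid_spec <- function(structure = NULL, spacing = 1, margin = 10,
                      origin = NULL, shape = NULL) {
  stopifnot(spacing > 0)
  if (is.null(origin)) {
    stopifnot(!is.null(structure))
    xyz <- as.matrix(structure[, c("x", "y", "z")])
    lo <- apply(xyz, 2, min) - margin
    hi <- apply(xyz, 2, max) + margin
    origin <- lo
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = as.integer(shape)), class = "grid_spec")
}

grid_points <- function(g) {
  ax <- lapply(1:3, function(i) g$origin[i] + (seq_len(g$shape[i]) - 1) * g$spacing)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# tensors for ensemble member m, keyed by dataset label, pooled over a
# list of ensembles (pcs_bootstrap or bare pcs_fit treated as 1 member)
member_tensors <- function(ensembles, m) {
  out <- list()
  for (e in ensembles) {
    f <- if (inherits(e, "pcs_bootstrap")) e$members[[min(m, e$n_members)]] else e
    out[names(f$tensors)] <- f$tensors
  }
  out
}

ensemble_size <- function(ensembles)
  max(vapply(ensembles, function(e)
    if (inherits(e, "pcs_bootstrap")) as.integer(e$n_members) else 1L, 0L))

#' PCS-RMSD scalar field
#'
#' At every grid node `x`, ensemble member `m` contributes
#' `RMSD_m(x) = sqrt(mean_d (delta_d - pcs(T_dm, x))^2)` over the target's
#' datasets `d`; the field is the mean of `RMSD_m` over the members, which
#' propagates the tensor uncertainty captured by the bootstrap.
#'
#' @param ensembles list of [pcs_bootstrap()] (or `pcs_fit`) objects
#'   covering all datasets named in `target_pcs`.
#' @param target_pcs named numeric vector: the target nucleus's observed
#'   PCS (ppm) per dataset label (`"site:tag:metal"`).
#' @param grid a [grid_spec()].
#' @return object of class `scalar_field`: the grid plus a 3D array
#'   `values` (ppm).
#' @export
rmsd_field <- function(ensembles, target_pcs, grid) {
  if (inherits(ensembles, c("pcs_bootstrap", "pcs_fit")))
    ensembles <- list(ensembles)
  labs <- names(target_pcs)
  stopifnot(length(labs) > 0, !is.null(labs))
  have <- unique(unlist(lapply(ensembles, function(e) {
    f <- if (inherits(e, "pcs_bootstrap")) e$full else e
    f$labels
  })))
  miss <- setdiff(labs, have)
  if (length(miss))
    stop("rmsd_field: no fitted tensor for dataset(s): ",
         paste(miss, collapse = ", "))
  G <- grid_points(grid)
  n_mem <- ensemble_size(ensembles)
  acc <- numeric(nrow(G))
  for (m in seq_len(n_mem)) {
    tens <- member_tensors(ensembles, m)
    sq <- numeric(nrow(G))
    for (l in labs)
      sq <- sq + (target_pcs[[l]] - pcs_forward(tens[[l]], G))^2
    acc <- acc + sqrt(sq / length(labs))
  }
  vals <- array(acc / n_mem, dim = grid$shape)
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 shape = grid$shape, values = vals),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf(
    "scalar_field: %d x %d x %d nodes, spacing %.2f A, min %.4f ppm\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing, min(x$values)))
  invisible(x)
}

#' Location and value of the field minimum
#'
#' @param field a `scalar_field`.
#' @return list with `position` (Angstrom) and `value` (ppm).
#' @export
field_minimum <- function(field) {
  i <- arrayInd(which.min(field$values), field$shape)
  list(position = field$origin + (as.numeric(i) - 1) * field$spacing,
       value = min(field$values))
}

#' Extract a localisation space from an RMSD field
#'
#' The localisation space is the set of grid nodes whose RMSD does not
#' exceed the cutoff — the region compatible with the observed PCSs
#' within that tolerance.
#'
#' @param field a `scalar_field`.
#' @param cutoff maximal RMSD, ppm (> 0).
#' @return object of class `localisation_space`: member points (n x 3),
#'   their field values, the `centroid`, and the `extent` (maximum
#'   pairwise distance). Empty spaces are allowed (with a warning).
#' @export
extract_space <- function(field, cutoff) {
  stopifnot(cutoff > 0)
  sel <- which(field$values <= cutoff)
  if (length(sel) == 0) {
    warning(sprintf(
      "empty localisation space: cutoff %.4g ppm below field minimum %.4g ppm",
      cutoff, min(field$values)))
    return(structure(list(cutoff = cutoff,
                          points = matrix(0, 0, 3), values = numeric(0),
                          centroid = rep(NA_real_, 3), extent = NA_real_,
                          n = 0L),
                     class = "localisation_space"))
  }
  idx <- arrayInd(sel, field$shape)
  pts <- sweep((idx - 1) * field$spacing, 2, field$origin, "+")
  colnames(pts) <- c("x", "y", "z")
  structure(list(cutoff = cutoff, points = pts,
                 values = field$values[sel],
                 centroid = colMeans(pts),
                 extent = point_set_diameter(pts),
                 n = nrow(pts)),
            class = "localisation_space")
}

# Maximum pairwise distance.  Exact O(n^2) for small sets; for large sets
# the diameter is computed over directional extreme points (the diameter
# is attained at convex-hull vertices, all of which are extreme in some
# direction; 312 probe directions make the approximation tight).
point_set_diameter <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(0)
  if (n > 2000) {
    k <- 312
    i <- seq_len(k)
    phi <- acos(1 - 2 * (i - 0.5) / k)
    th <- pi * (1 + sqrt(5)) * i
    dirs <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    proj <- pts %*% t(dirs)
    cand <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
    pts <- pts[cand, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' @export
print.localisation_space <- function(x, ...) {
  if (x$n == 0) {
    cat(sprintf("localisation_space: empty (cutoff %.4g ppm)\n", x$cutoff))
  } else {
    cat(sprintf(
      "localisation_space: %d nodes <= %.4g ppm; centroid (%.2f, %.2f, %.2f), extent %.2f A\n",
      x$n, x$cutoff, x$centroid[1], x$centroid[2], x$centroid[3], x$extent))
  }
  invisible(x)
}

#' Compare two localisation spaces
#'
#' @param a,b nonempty [extract_space()] results on a common grid.
#' @return list with `centroid_distance` (Angstrom) and
#'   `overlap_fraction` = |A intersect B| / min(|A|, |B|).
#' @export
space_metrics <- function(a, b) {
  if (a$n == 0 || b$n == 0)
    stop("space_metrics: empty localisation space")
  keys <- function(s) apply(round(s$points, 6), 1, paste, collapse = "/")
  inter <- length(intersect(keys(a), keys(b)))
  list(centroid_distance = vnorm(a$centroid - b$centroid),
       overlap_fraction = inter / min(a$n, b$n))
}

#' Intersection angle of two PCS isosurfaces
#'
#' The acute angle between the PCS gradients of two tensors at a point —
#' the local intersection angle of the isosurfaces through that point.
#' Localisation is well conditioned where isosurfaces cross near 90
#' degrees and degrades sharply where they are near-parallel.
#'
#' @param tensorA,tensorB [chi_tensor()] objects.
#' @param point length-3 position, Angstrom.
#' @return angle in degrees, in `[0, 90]`.
#' @export
isosurface_angle <- function(tensorA, tensorB, point) {
  g1 <- pcs_gradient(tensorA, point)
  g2 <- pcs_gradient(tensorB, point)
  n1 <- vnorm(g1); n2 <- vnorm(g2)
  if (n1 == 0 || n2 == 0)
    stop("isosurface_angle: zero PCS gradient, angle undefined")
  deg(acos(min(1, abs(sum(g1 * g2)) / (n1 * n2))))
}

#' Pairwise isosurface-angle report with dataset-selection policy
#'
#' Computes the RMSD-field minimum, evaluates all pairwise isosurface
#' intersection angles there (using ensemble-mean tensors), and flags
#' pairs from the same site and tag but different metals whose angle
#' falls below the threshold — the pathological configuration in which
#' two tensors of different magnitude and sign but closely similar
#' orientation constrain the target along nearly the same direction. The
#' default policy excludes the smaller-|dax| member of each flagged pair.
#'
#' @param ensembles list of [pcs_bootstrap()] / `pcs_fit` objects.
#' @param target_pcs named PCS vector, as in [rmsd_field()].
#' @param grid a [grid_spec()].
#' @param threshold flag pairs below this angle, degrees (default 20).
#' @return data.frame of pairs (labels, angle, same-site/tag flags,
#'   `flagged`), with attributes `"minimum"` (field minimum) and
#'   `"excluded"` (labels the policy drops).
#' @export
dataset_selection_report <- function(ensembles, target_pcs, grid,
                                     threshold = 20) {
  if (inherits(ensembles, c("pcs_bootstrap", "pcs_fit")))
    ensembles <- list(ensembles)
  field <- rmsd_field(ensembles, target_pcs, grid)
  mn <- field_minimum(field)
  tens <- list()
  for (e in ensembles) {
    tl <- if (inherits(e, "pcs_bootstrap")) mean_tensors(e) else e$tensors
    tens[names(tl)] <- tl
  }
  labs <- names(target_pcs)
  if (length(labs) < 2) {
    out <- data.frame(label_a = character(), label_b = character(),
                      angle = numeric(), same_site_tag = logical(),
                      flagged = logical())
    attr(out, "minimum") <- mn
    attr(out, "excluded") <- character()
    return(out)
  }
  parts <- strsplit(labs, ":", fixed = TRUE)
  st <- vapply(parts, function(p) paste(p[1], p[2], sep = ":"), "")
  metal <- vapply(parts, function(p) p[3], "")
  pair <- utils::combn(seq_along(labs), 2)
  rows <- apply(pair, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ang <- isosurface_angle(tens[[labs[i]]], tens[[labs[j]]], mn$position)
    same <- st[i] == st[j] && metal[i] != metal[j]
    data.frame(label_a = labs[i], label_b = labs[j], angle = ang,
               same_site_tag = same,
               flagged = same && ang < threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  excl <- character()
  for (k in which(out$flagged)) {
    la <- out$label_a[k]; lb <- out$label_b[k]
    daxs <- vapply(list(tens[[la]], tens[[lb]]),
                   function(t) abs(principal_form(t)$dax), 0)
    excl <- union(excl, if (daxs[1] >= daxs[2]) lb else la)
  }
  attr(out, "minimum") <- mn
  attr(out, "excluded") <- excl
  out
}

# Spatially thinned lowest-value grid nodes, used to seed the global
# basin search: RMSD basins can be narrower than the coarse spacing, so
# the global grid minimum alone is not a reliable basin selector.
candidate_minima <- function(field, n_candidates = 30, thin = 2) {
  ord <- order(field$values)[seq_len(min(length(field$values), 4000))]
  idx <- arrayInd(ord, field$shape)
  pts <- sweep((idx - 1) * field$spacing, 2, field$origin, "+")
  keep <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(pts))) {
    if (nrow(keep) == 0 ||
        min(sqrt(rowSums(sweep(keep, 2, pts[i, ])^2))) >= thin)
      keep <- rbind(keep, pts[i, ])
    if (nrow(keep) >= n_candidates) break
  }
  keep
}

# ensemble-mean tensors per dataset label (cheap surrogate for polishing)
pooled_mean_tensors <- function(ensembles) {
  out <- list()
  for (e in ensembles) {
    tl <- if (inherits(e, "pcs_bootstrap")) mean_tensors(e) else e$tensors
    out[names(tl)] <- tl
  }
  out
}

#' Localise a target nucleus
#'
#' Convenience wrapper running the full localisation stage: a coarse RMSD
#' field over the structure; a global basin search that polishes the
#' lowest coarse nodes by direct minimisation (the RMSD basins can be
#' sharper than the coarse spacing, so refining only around the single
#' lowest node is unreliable); a fine-grid pass around the best basin;
#' and the cutoff extraction. The default cutoff is
#' `field minimum + 0.5 * noise`, with the noise estimated from the
#' full-fit RMS residual when not supplied.
#'
#' @param ensembles list of [pcs_bootstrap()] / `pcs_fit` objects.
#' @param target_pcs named PCS vector (ppm) for one nucleus.
#' @param structure a [structure_model()] defining the search region.
#' @param spacing,margin coarse grid parameters (default 1 and 10 A).
#' @param refine logical: run the basin search and fine pass (default
#'   TRUE).
#' @param refine_spacing,refine_box fine-grid spacing and cube edge
#'   (defaults 0.25 and 6 A) around the winning basin.
#' @param n_candidates coarse nodes seeded into the basin search
#'   (default 30).
#' @param cutoff maximal RMSD in ppm; `NULL` for the default rule.
#' @param cutoff_offset if set (ppm) and `cutoff` is `NULL`, the cutoff
#'   is `field minimum + cutoff_offset` — a boundary a fixed number of
#'   noise standard deviations above the uncertainty floor of the
#'   averaged field.
#' @param noise_estimate experimental noise (ppm) for the cutoff rule.
#' @return object of class `pcs_localisation`: `field` (coarse),
#'   `refined` (fine field or NULL), `minimum`, `space`, `cutoff`.
#' @export
localise <- function(ensembles, target_pcs, structure, spacing = 1,
                     margin = 10, refine = TRUE, refine_spacing = 0.25,
                     refine_box = 6, cutoff = NULL, cutoff_offset = NULL,
                     noise_estimate = NULL, n_candidates = 30) {
  if (inherits(ensembles, c("pcs_bootstrap", "pcs_fit")))
    ensembles <- list(ensembles)
  coarse <- rmsd_field(ensembles, target_pcs, grid_spec(structure, spacing,
                                                        margin))
  mn <- field_minimum(coarse)
  fine <- NULL
  if (refine) {
    labs <- names(target_pcs)
    mt <- pooled_mean_tensors(ensembles)[labs]
    surrogate <- function(p) {
      sq <- vapply(labs, function(l)
        (target_pcs[[l]] - pcs_forward(mt[[l]], p))^2, 0)
      sqrt(mean(sq))
    }
    cands <- candidate_minima(coarse, n_candidates, thin = 2 * spacing)
    polished <- t(apply(cands, 1, function(p)
      stats::optim(p, surrogate, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-10))$par))
    score <- rmsd_at(ensembles, target_pcs, polished)
    # structural plausibility, applied when competing basins tie on the
    # RMSD statistic: a protein proton lies in the molecular region
    # (within `margin` of an actual atom, not merely inside the bounding
    # box whose corners sit far from the molecule) and cannot clash with
    # atoms already present (closer than H-H van der Waals contact)
    xyz <- as.matrix(structure[, c("x", "y", "z")])
    dmin <- apply(polished, 1, function(p)
      min(sqrt(colSums((t(xyz) - p)^2))))
    plausible <- dmin <= margin & dmin >= 2.5
    if (any(plausible)) score[!plausible] <- Inf
    best <- polished[which.min(score), ]
    half <- refine_box / 2
    g <- grid_spec(spacing = refine_spacing,
                   origin = best - half,
                   shape = rep(as.integer(round(refine_box / refine_spacing)) + 1L, 3))
    fine <- rmsd_field(ensembles, target_pcs, g)
    mn <- field_minimum(fine)
  }
  if (is.null(cutoff) && !is.null(cutoff_offset)) {
    cutoff <- mn$value + cutoff_offset
  }
  if (is.null(cutoff)) {
    if (is.null(noise_estimate)) {
      res <- unlist(lapply(ensembles, function(e) {
        f <- if (inherits(e, "pcs_bootstrap")) e$full else e
        f$residuals
      }))
      noise_estimate <- sqrt(mean(res^2))
    }
    cutoff <- mn$value + 0.5 * noise_estimate
  }
  space <- extract_space(fine %||% coarse, cutoff)
  structure(list(field = coarse, refined = fine, minimum = mn,
                 space = space, cutoff = cutoff,
                 noise_estimate = noise_estimate),
            class = "pcs_localisation")
}

#' @export
print.pcs_localisation <- function(x, ...) {
  cat(sprintf("pcs_localisation: minimum %.4f ppm at (%.2f, %.2f, %.2f)\n",
              x$minimum$value, x$minimum$position[1], x$minimum$position[2],
              x$minimum$position[3]))
  cat("  "); print(x$space)
  invisible(x)
}

#' Export a localisation space for molecular-graphics programs
#'
#' Writes the RMSD field as an OpenDX scalar grid and the localisation
#' space as a PDB of pseudo-atoms whose B-factor column carries the field
#' value, ready for isosurface and sphere rendering.
#'
#' @param space a nonempty [extract_space()] result.
#' @param field the `scalar_field` it was cut from.
#' @param dx_path,pdb_path output paths (`NULL` skips that file).
#' @return invisible character vector of the files written.
#' @export
export_space <- function(space, field, dx_path = NULL, pdb_path = NULL) {
  if (space$n == 0) stop("export_space: empty localisation space")
  written <- character()
  if (!is.null(dx_path)) {
    write_dx(field, dx_path)
    written <- c(written, dx_path)
  }
  if (!is.null(pdb_path)) {
    model <- structure_model(data.frame(
      chain = "L", resno = seq_len(space$n), resid = "LOC", elety = "DU",
      x = space$points[, 1], y = space$points[, 2],
      z = space$points[, 3], stringsAsFactors = FALSE),
      label = "localisation")
    write_structure(model, pdb_path, b = space$values, hetatm = TRUE)
    written <- c(written, pdb_path)
  }
  invisible(written)
}

#' Write a scalar field in OpenDX format
#'
#' @param field a `scalar_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(field, path) {
  n <- field$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by pcsloc",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", field$origin[1], field$origin[2],
            field$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", field$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", field$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", field$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  v <- as.vector(aperm(field$values, c(3, 2, 1)))  # z fastest, x slowest
  pad <- (-length(v)) %% 3
  v3 <- matrix(c(sprintf("%.6e", v), rep("", pad)), nrow = 3)
  writeLines(trimws(apply(v3, 2, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "pcs-rmsd (ppm)" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path an OpenDX file as written by [write_dx()].
#' @return a `scalar_field`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) lines[grepl(pat, lines)][1]
  counts <- as.integer(strsplit(trimws(sub(".*counts", "",
             grab("gridpositions"))), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("origin", "",
             grab("^origin"))), "\\s+")[[1]])
  deltas <- lines[grepl("^delta", lines)]
  d1 <- as.numeric(strsplit(trimws(sub("delta", "", deltas[1])), "\\s+")[[1]])
  start <- which(grepl("data follows", lines)) + 1
  end <- which(grepl("^attribute", lines))[1] - 1
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  v <- v[seq_len(prod(counts))]
  vals <- aperm(array(v, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = origin, spacing = d1[1], shape = counts,
                 values = vals), class = "scalar_field")
}
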