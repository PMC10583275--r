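# Delta-chi tensor fitting.  At a fixed metal position the PCS is linear
# in the five Cartesian tensor components, so the fit separates into an
# inner linear least-squares solve per dataset and an outer nonlinear
# search over the three metal coordinates, pooled over all datasets that
# share a tagging site (e.g. Tb and Tm data from the same tag).

#' Q factor of a fit
#'
#' `Q = sqrt(sum((obs - calc)^2) / sum(obs^2))`; 0 for perfect agreement,
#' 1 when the model predicts nothing (all zeros).
#'
#' @param observed,calculated equal-length numeric vectors, ppm.
#' @return dimensionless Q factor.
#' @export
q_factor <- function(observed, calculated) {
  stopifnot(length(observed) == length(calculated))
  ss_obs <- sum(observed^2)
  if (ss_obs == 0) stop("Q factor undefined: all observed values are zero")
  sqrt(sum((observed - calculated)^2) / ss_obs)
}

#' Linear tensor-component fit at a fixed metal position
#'
#' Solves the 5-parameter linear least-squares problem for the Cartesian
#' tensor components given a known metal position.
#'
#' @param metal_position length-3 numeric, Angstrom.
#' @param dataset a [pcs_dataset()].
#' @param structure a [structure_model()] providing the atom coordinates
#'   (alternatively, pass the matched coordinates via `atom_positions` and
#'   `values`).
#' @param atom_positions,values optional explicit n x 3 coordinate matrix
#'   and PCS vector, bypassing the structure join.
#' @return a [chi_tensor()] at `metal_position`.
#' @export
fit_components_linear <- function(metal_position, dataset = NULL,
                                  structure = NULL, atom_positions = NULL,
                                  values = NULL) {
  if (is.null(atom_positions)) {
    md <- match_dataset(dataset, structure)
    atom_positions <- md$positions
    values <- md$values
  }
  n <- length(values)
  if (n < 5)
    stop(sprintf("underdetermined: %d PCS value(s) matched, need at least 5", n))
  A <- pcs_design(metal_position, atom_positions)
  qr_A <- qr(A)
  if (qr_A$rank < 5)
    stop("rank-deficient design: atom geometry does not determine the tensor")
  comp <- qr.coef(qr_A, values)
  chi_tensor(metal_position, comp)
}

# Pooled residual sum of squares over datasets at metal position p, with
# the inner linear solve profiled out.  `matched` is a list of
# list(positions, values).  Returns the objective, optionally with
# tensors/gradient via attributes.
pooled_objective <- function(p, matched, want = "value") {
  total <- 0
  grad <- c(0, 0, 0)
  tensors <- vector("list", length(matched))
  for (i in seq_along(matched)) {
    m <- matched[[i]]
    A <- pcs_design(p, m$positions)
    fit <- .lm.fit(A, m$values)
    res <- fit$residuals
    total <- total + sum(res^2)
    if (want != "value") {
      tens <- chi_tensor(p, fit$coefficients)
      tensors[[i]] <- tens
      if (want == "gradient" || want == "all") {
        # envelope theorem: components are optimal, so only the explicit
        # position dependence contributes; d(delta)/d(metal) = -grad_nucleus
        G <- pcs_gradient(tens, m$positions)
        grad <- grad + 2 * colSums(res * G)
      }
    }
  }
  if (want == "value") return(total)
  list(value = total, gradient = grad, tensors = tensors)
}

# 26 lattice directions (cube faces, edges, corners), unit length.
shell_directions <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g / sqrt(rowSums(g^2))
}

#' Fit a common metal position and per-dataset tensors
#'
#' The central model fit: all datasets from one tagging site (typically the
#' Tb and Tm data of the same tag) share a single paramagnetic-centre
#' position; each dataset gets its own anisotropy tensor. The outer search
#' over the position minimises the pooled sum of squared PCS residuals by
#' BFGS with an analytic (profiled) gradient; unless disabled, a
#' multi-start screen over a spherical shell of radius 4-14 Angstrom
#' around the start hint guards against mirror-image local minima.
#'
#' @param datasets a [pcs_dataset()] or list of them (one tagging site).
#' @param structure a [structure_model()] carrying the amide protons.
#' @param site_residue residue number of the tagged cysteine; its CB atom
#'   provides the default start hint and the reported metal-CB distance.
#' @param start optional explicit start position (overrides the hint).
#' @param multi_start logical; screen shell starts (default TRUE).
#' @param shell_radii radii of the multi-start shell, Angstrom.
#' @param n_polish number of best screened starts to polish with BFGS.
#' @param control passed to [stats::optim()] (defaults:
#'   `reltol = 1e-12`, `maxit = 500`).
#' @return an object of class `pcs_fit`: the optimised position, one
#'   [chi_tensor()] per dataset, pooled and per-dataset Q factors,
#'   residuals, and the metal-CB distance when `site_residue` is given.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `fitted`, `plot`.
#' @export
pcs_fit <- function(datasets, structure, site_residue = NULL, start = NULL,
                    multi_start = TRUE, shell_radii = seq(4, 14, by = 2),
                    n_polish = 3, control = list()) {
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  labels <- vapply(datasets, dataset_label, "")
  sites <- vapply(datasets, function(d) attr(d, "site"), "")
  if (length(unique(sites)) > 1)
    stop("pcs_fit: datasets must share one tagging site (got: ",
         paste(unique(sites), collapse = ", "), ")")
  matched <- lapply(datasets, match_dataset, model = structure)
  for (i in seq_along(matched))
    if (length(matched[[i]]$values) < 5)
      stop(sprintf("underdetermined: dataset %s has %d matched PCS value(s)",
                   labels[i], length(matched[[i]]$values)))

  cb <- NULL
  if (!is.null(site_residue)) {
    hit <- which(structure$resno == site_residue & structure$elety == "CB")
    if (length(hit) == 1) cb <- unlist(structure[hit, c("x", "y", "z")],
                                       use.names = FALSE)
  }
  hint <- start %||% cb %||%
    colMeans(do.call(rbind, lapply(matched, `[[`, "positions")))

  obj <- function(p) pooled_objective(p, matched, "value")
  grd <- function(p) pooled_objective(p, matched, "gradient")$gradient

  starts <- matrix(hint, nrow = 1)
  if (multi_start) {
    dirs <- shell_directions()
    shell <- do.call(rbind, lapply(shell_radii, function(r)
      sweep(dirs * r, 2, hint, "+")))
    vals <- apply(shell, 1, obj)
    starts <- rbind(starts, shell[order(vals)[seq_len(n_polish)], , drop = FALSE])
  }
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 500), control)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, grd, method = "BFGS", control = ctrl)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value > obj(hint) + 1e-9)
    stop("position search failed to improve on the start hint; ",
         sprintf("best objective %.3g at (%.2f, %.2f, %.2f)", best$value,
                 best$par[1], best$par[2], best$par[3]))

  final <- pooled_objective(best$par, matched, "all")
  tensors <- stats::setNames(final$tensors, labels)
  obs <- unlist(lapply(matched, `[[`, "values"))
  calc <- unlist(lapply(seq_along(matched), function(i)
    pcs_forward(tensors[[i]], matched[[i]]$positions)))
  per_q <- vapply(seq_along(matched), function(i)
    q_factor(matched[[i]]$values,
             pcs_forward(tensors[[i]], matched[[i]]$positions)), 0)
  structure(list(
    position = best$par,
    tensors = tensors,
    labels = labels,
    site = sites[1],
    matched = matched,
    observed = obs,
    calculated = calc,
    residuals = obs - calc,
    n_points = length(obs),
    q_factor = q_factor(obs, calc),
    q_per_dataset = stats::setNames(per_q, labels),
    objective = best$value,
    convergence = best$convergence,
    cb_position = cb,
    metal_cb_distance = if (!is.null(cb)) vnorm(best$par - cb) else NA_real_
  ), class = "pcs_fit")
}

#' @export
print.pcs_fit <- function(x, ...) {
  cat(sprintf("pcs_fit: site %s, %d dataset(s), %d PCS values\n",
              x$site, length(x$tensors), x$n_points))
  cat(sprintf("  metal position: %8.3f %8.3f %8.3f", x$position[1],
              x$position[2], x$position[3]))
  if (!is.na(x$metal_cb_distance))
    cat(sprintf("   (%.2f A from CB)", x$metal_cb_distance))
  cat(sprintf("\n  pooled Q = %.4f\n", x$q_factor))
  invisible(x)
}

#' @export
summary.pcs_fit <- function(object, ...) {
  tab <- coef(object)
  cat(sprintf("Common-position Delta-chi tensor fit, site %s\n", object$site))
  cat(sprintf("Metal position (A): %.3f %.3f %.3f", object$position[1],
              object$position[2], object$position[3]))
  if (!is.na(object$metal_cb_distance))
    cat(sprintf(";  metal-CB distance %.2f A", object$metal_cb_distance))
  cat("\n\nTensors (Dchi in 1e-32 m^3, Euler ZYZ in degrees):\n")
  print(round(tab, 3))
  cat(sprintf("\nPooled Q = %.4f over %d PCS values; RMS residual %.4f ppm\n",
              object$q_factor, object$n_points,
              sqrt(mean(object$residuals^2))))
  invisible(tab)
}

#' Tensor parameters of a fit
#'
#' @param object a `pcs_fit`.
#' @param ... unused.
#' @return matrix with one row per dataset: `dax`, `drh`, Euler angles
#'   (degrees), and per-dataset Q.
#' @export
coef.pcs_fit <- function(object, ...) {
  rows <- lapply(object$tensors, function(t) {
    p <- principal_form(t)
    c(dax = p$dax, drh = p$drh, alpha = deg(p$euler[[1]]),
      beta = deg(p$euler[[2]]), gamma = deg(p$euler[[3]]))
  })
  tab <- do.call(rbind, rows)
  cbind(tab, Q = object$q_per_dataset)
}

#' Back-calculate PCS values from a fit
#'
#' @param object a `pcs_fit`.
#' @param newdata n x 3 coordinate matrix, or a [structure_model()] /
#'   atom data.frame with x, y, z columns. Omitted: fitted values.
#' @param ... unused.
#' @return matrix of PCS (ppm), one column per dataset tensor.
#' @export
predict.pcs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- if (is.data.frame(newdata)) atom_xyz(newdata) else as_xyz_matrix(newdata)
  out <- vapply(object$tensors, function(t) pcs_forward(t, X),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = list(NULL, object$labels))
}

#' @export
fitted.pcs_fit <- function(object, ...) object$calculated

#' @export
residuals.pcs_fit <- function(object, ...) object$residuals

#' Observed versus back-calculated PCS correlation plot
#'
#' @param x a `pcs_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pcs_fit <- function(x, ...) {
  nd <- length(x$tensors)
  cols <- grDevices::hcl.colors(max(nd, 2), "Dark 3")
  grp <- rep(seq_len(nd), vapply(x$matched, function(m) length(m$values), 0L))
  lim <- range(x$observed, x$calculated)
  graphics::plot(x$observed, x$calculated, col = cols[grp], pch = 16,
                 xlim = lim, ylim = lim,
                 xlab = "observed PCS (ppm)",
                 ylab = "back-calculated PCS (ppm)",
                 main = sprintf("site %s, Q = %.3f", x$site, x$q_factor), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = x$labels, col = cols[seq_len(nd)],
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Rank candidate structures by fit quality
#'
#' Fits the tensors to each candidate structure and ranks by the pooled Q
#' factor over all datasets (datasets are grouped by tagging site, each
#' group sharing a common metal position). Ties keep input order; a
#' candidate whose fit fails is reported as failed and does not disturb
#' the others.
#'
#' @param datasets list of [pcs_dataset()] (may span several sites).
#' @param candidate_structures named list of [structure_model()].
#' @param site_residues optional named vector mapping site label to the
#'   tagged residue number (start hints).
#' @param ... passed to [pcs_fit()].
#' @return data.frame (structure label, Q, ok, winner) sorted by ascending
#'   Q with failed candidates last.
#' @export
rank_structures <- function(datasets, candidate_structures,
                            site_residues = NULL, ...) {
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  labels <- names(candidate_structures) %||%
    paste0("structure", seq_along(candidate_structures))
  sites <- vapply(datasets, function(d) attr(d, "site"), "")
  rows <- lapply(seq_along(candidate_structures), function(i) {
    q <- tryCatch({
      qs <- lapply(unique(sites), function(s) {
        fit <- pcs_fit(datasets[sites == s], candidate_structures[[i]],
                       site_residue = if (!is.null(site_residues))
                         site_residues[[s]] else NULL, ...)
        list(obs = fit$observed, calc = fit$calculated)
      })
      q_factor(unlist(lapply(qs, `[[`, "obs")),
               unlist(lapply(qs, `[[`, "calc")))
    }, error = function(e) NA_real_)
    data.frame(structure_label = labels[i], Q = q, ok = !is.na(q),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(!out$ok, out$Q)       # failed rows last; stable for ties
  out <- out[ord, , drop = FALSE]
  out$winner <- FALSE
  if (any(out$ok)) out$winner[1] <- TRUE
  rownames(out) <- NULL
  out
}
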