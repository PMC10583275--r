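# Bootstrap propagation of tensor uncertainty: repeat the fit with a
# fixed fraction of the backbone PCS data randomly omitted, and carry the
# resulting tensor ensemble through the localisation stage.

#' Bootstrap ensemble of tensor fits
#'
#' Repeats [pcs_fit()] `n_members` times, each time keeping a uniform
#' random subset of `ceiling((1 - omission_fraction) * N)` PCS values per
#' dataset (drawn without replacement, independently per dataset). Member
#' `m` draws from a stream seeded by `(seed, m)`, so the ensemble is
#' reproducible and individual members can be regenerated. Member fits
#' start from the full-fit position (no multi-start).
#'
#' @param datasets a [pcs_dataset()] or list of them (one tagging site).
#' @param structure a [structure_model()].
#' @param n_members ensemble size (default 20).
#' @param omission_fraction fraction of data omitted per member (default
#'   0.2).
#' @param seed integer root seed.
#' @param ... passed to [pcs_fit()] (e.g. `site_residue`).
#' @return object of class `pcs_bootstrap`: `full` (the all-data
#'   `pcs_fit`), `members` (list of `pcs_fit`), and the ensemble
#'   parameters.
#' @export
pcs_bootstrap <- function(datasets, structure, n_members = 20,
                          omission_fraction = 0.2, seed = 1, ...) {
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  stopifnot(n_members >= 1, omission_fraction > 0, omission_fraction < 1)
  full <- pcs_fit(datasets, structure, ...)
  for (d in datasets) {
    n_keep <- ceiling((1 - omission_fraction) * nrow(d))
    if (n_keep < 5)
      stop(sprintf("dataset %s: only %d points would remain after omission",
                   dataset_label(d), n_keep))
  }
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    sub <- with_seed(sub_seed(seed, "bootstrap", m), {
      lapply(datasets, function(d) {
        n_keep <- ceiling((1 - omission_fraction) * nrow(d))
        d[sort(sample.int(nrow(d), n_keep)), , drop = FALSE]
      })
    })
    for (i in seq_along(sub))
      attributes(sub[[i]])[c("class", "site", "tag", "metal", "label")] <-
        attributes(datasets[[i]])[c("class", "site", "tag", "metal", "label")]
    members[[m]] <- pcs_fit(sub, structure, start = full$position,
                            multi_start = FALSE, ...)
  }
  structure(list(full = full, members = members, n_members = n_members,
                 omission_fraction = omission_fraction, seed = seed),
            class = "pcs_bootstrap")
}

#' @export
print.pcs_bootstrap <- function(x, ...) {
  pos <- t(vapply(x$members, `[[`, numeric(3), "position"))
  spread <- sqrt(mean(rowSums(sweep(pos, 2, x$full$position)^2)))
  cat(sprintf(
    "pcs_bootstrap: %d members, %.0f%% omission, seed %d (site %s)\n",
    x$n_members, 100 * x$omission_fraction, x$seed, x$full$site))
  cat(sprintf("  full-fit Q = %.4f; RMS member position spread = %.3f A\n",
              x$full$q_factor, spread))
  invisible(x)
}

#' @export
summary.pcs_bootstrap <- function(object, ...) {
  print(object)
  qs <- vapply(object$members, `[[`, 0, "q_factor")
  cat(sprintf("  member Q: %.4f - %.4f (median %.4f)\n",
              min(qs), max(qs), stats::median(qs)))
  invisible(object)
}

# Average tensors over ensemble members (component-wise; the PCS model is
# linear in the components, positions averaged too).  Used for reporting
# and for the intersection-angle diagnostic.
mean_tensors <- function(ensemble) {
  labs <- ensemble$full$labels
  stats::setNames(lapply(labs, function(l) {
    comp <- rowMeans(vapply(ensemble$members,
                            function(f) f$tensors[[l]]$components, numeric(5)))
    pos <- rowMeans(vapply(ensemble$members,
                           function(f) f$tensors[[l]]$position, numeric(3)))
    chi_tensor(pos, comp)
  }), labs)
}
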