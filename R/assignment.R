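# Resonance assignment by PCS matching: observed paramagnetically
# shifted peaks are assigned to candidate nuclei by exact minimum-cost
# one-to-one matching of predicted versus observed PCS patterns, with a
# qualitative PRE proximity screen for peaks broadened beyond detection.

#' Predicted PCS table for candidate nuclei
#'
#' @param tensors named list of [chi_tensor()], one per dataset.
#' @param candidate_atoms a [structure_model()] subset / atom data.frame
#'   (rows are candidates) or an n x 3 coordinate matrix.
#' @param candidate_names optional row labels.
#' @return candidates x datasets matrix of PCS (ppm).
#' @export
predict_pcs_table <- function(tensors, candidate_atoms,
                              candidate_names = NULL) {
  X <- if (is.data.frame(candidate_atoms)) atom_xyz(candidate_atoms)
       else as_xyz_matrix(candidate_atoms)
  if (is.null(candidate_names) && is.data.frame(candidate_atoms))
    candidate_names <- paste0(candidate_atoms$resno, ".",
                              candidate_atoms$elety)
  out <- vapply(tensors, function(t) pcs_forward(t, X), numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(candidate_names, names(tensors)))
  out
}

# Exact minimum-cost one-to-one matching of rows (observations) to
# columns (candidates) by dynamic programming over candidate subsets;
# exponential in the number of candidates, exact and fast for the peak
# counts that occur in practice (<= ~16).
dp_assign <- function(cost) {
  n_obs <- nrow(cost); n_cand <- ncol(cost)
  stopifnot(n_obs <= n_cand)
  if (n_cand > 16)
    stop("assignment problems with more than 16 candidates are not supported")
  n_mask <- bitwShiftL(1L, n_cand)
  INF <- Inf
  # best[mask] = minimal cost of assigning the first popcount-limited
  # observations; iterate observations outermost
  best <- rep(INF, n_mask); best[1] <- 0
  choice <- matrix(NA_integer_, n_obs, n_mask)
  for (i in seq_len(n_obs)) {
    nxt <- rep(INF, n_mask)
    active <- which(is.finite(best)) - 1L
    for (mask in active) {
      b <- best[mask + 1L]
      for (j in seq_len(n_cand)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L && is.finite(cost[i, j])) {
          v <- b + cost[i, j]
          if (v < nxt[mask + bit + 1L]) {
            nxt[mask + bit + 1L] <- v
            choice[i, mask + bit + 1L] <- j
          }
        }
      }
    }
    best <- nxt
  }
  m <- which.min(best)
  if (!is.finite(best[m])) return(NULL)
  total <- best[m]
  sel <- integer(n_obs)
  mask <- m - 1L
  for (i in rev(seq_len(n_obs))) {
    j <- choice[i, mask + 1L]
    sel[i] <- j
    mask <- mask - bitwShiftL(1L, j - 1L)
  }
  list(assignment = sel, total = total)
}

#' Assign observed peaks to candidate nuclei
#'
#' Global minimum-cost one-to-one matching between observed peaks and
#' candidate atoms, with `cost(i, j)` the mean squared difference between
#' observed and predicted PCS over the datasets both share (peaks with
#' missing values in some datasets are matched on the rest). The exact
#' second-best matching is also computed; the result is flagged ambiguous
#' when it comes within 10% of the optimum.
#'
#' @param predicted candidates x datasets matrix from
#'   [predict_pcs_table()].
#' @param observations peaks x datasets matrix (or data.frame) of
#'   observed PCS, `NA` for unobserved values; row names label the peaks.
#' @param forbidden optional logical peaks x candidates matrix; `TRUE`
#'   forbids the pairing (e.g. PRE-broadened candidates for observed
#'   peaks).
#' @return list: `assignment` (data.frame peak, candidate, cost),
#'   `total_cost`, `second_best`, `ambiguous`.
#' @export
assign_peaks <- function(predicted, observations, forbidden = NULL) {
  obs <- as.matrix(observations)
  if (is.null(rownames(obs))) rownames(obs) <- paste0("peak", seq_len(nrow(obs)))
  if (nrow(obs) > nrow(predicted))
    stop("more observations than candidates")
  shared <- intersect(colnames(obs) %||% colnames(predicted),
                      colnames(predicted))
  if (is.null(colnames(obs))) {
    stopifnot(ncol(obs) == ncol(predicted))
    colnames(obs) <- colnames(predicted)
    shared <- colnames(predicted)
  }
  if (length(shared) == 0)
    stop("observations share no dataset with the predictions")
  obs <- obs[, shared, drop = FALSE]
  pred <- predicted[, shared, drop = FALSE]
  if (any(rowSums(!is.na(obs)) == 0))
    stop("observation(s) with no values in any shared dataset: ",
         paste(rownames(obs)[rowSums(!is.na(obs)) == 0], collapse = ", "))
  n_obs <- nrow(obs); n_cand <- nrow(pred)
  cost <- matrix(0, n_obs, n_cand)
  for (i in seq_len(n_obs)) {
    ok <- !is.na(obs[i, ])
    d2 <- sweep(pred[, ok, drop = FALSE], 2, obs[i, ok])^2
    cost[i, ] <- rowMeans(d2)
  }
  if (!is.null(forbidden)) cost[forbidden] <- Inf
  sol <- dp_assign(cost)
  if (is.null(sol)) stop("no feasible assignment (all pairings forbidden?)")
  # exact second best: force each optimal pairing off in turn
  second <- Inf
  for (i in seq_len(n_obs)) {
    c2 <- cost
    c2[i, sol$assignment[i]] <- Inf
    alt <- dp_assign(c2)
    if (!is.null(alt) && alt$total < second) second <- alt$total
  }
  pair_cost <- cost[cbind(seq_len(n_obs), sol$assignment)]
  out <- data.frame(
    peak = rownames(obs),
    candidate = (rownames(predicted) %||%
                   paste0("cand", seq_len(n_cand)))[sol$assignment],
    candidate_index = sol$assignment,
    cost = pair_cost,
    stringsAsFactors = FALSE)
  list(assignment = out, total_cost = sol$total, second_best = second,
       ambiguous = is.finite(second) && second <= 1.1 * sol$total)
}

#' PRE proximity screen
#'
#' Nuclei close to the paramagnetic centre are broadened beyond detection
#' by paramagnetic relaxation enhancement; this qualitative screen flags
#' candidates within `radius` of the metal so that missing peaks can be
#' rationalised and forbidden pairings constructed for [assign_peaks()].
#'
#' @param metal_position length-3, Angstrom.
#' @param candidate_atoms atom data.frame or n x 3 matrix.
#' @param radius flag radius, Angstrom (default 13).
#' @return logical vector: `TRUE` = expected broadened / unobservable.
#' @export
pre_screen <- function(metal_position, candidate_atoms, radius = 13) {
  stopifnot(radius > 0)
  X <- if (is.data.frame(candidate_atoms)) atom_xyz(candidate_atoms)
       else as_xyz_matrix(candidate_atoms)
  sqrt(rowSums(sweep(X, 2, metal_position)^2)) < radius
}
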