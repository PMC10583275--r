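# PCS datasets: one labelled table of per-atom pseudocontact shifts per
# {tagging site, tag, metal}, read and written in the whitespace-column
# "NPC" dialect: residue_number atom_name value error, '#' comments.

#' Create a PCS dataset
#'
#' PCS values are paramagnetic-minus-diamagnetic chemical shifts in ppm,
#' keyed by residue number and atom name.
#'
#' @param site_label tagging-site label (e.g. `"N172C"`).
#' @param tag_label tag chemistry label (e.g. `"C2"`, `"C12"`,
#'   `"synthetic"`).
#' @param metal_label lanthanoid label (e.g. `"Tb"`, `"Tm"`).
#' @param values data.frame with columns `resno`, `elety`, `value` (ppm)
#'   and optionally `error` (ppm, default 0).
#' @return data.frame of class `pcs_dataset` with attributes `site`,
#'   `tag`, `metal` and `label` (`"site:tag:metal"`).
#' @export
pcs_dataset <- function(site_label, tag_label, metal_label, values) {
  stopifnot(nzchar(site_label), nzchar(tag_label), nzchar(metal_label))
  need <- c("resno", "elety", "value")
  if (!all(need %in% names(values)))
    stop("pcs_dataset: values needs columns resno, elety, value")
  if (nrow(values) == 0) stop("pcs_dataset: empty dataset")
  if (is.null(values$error)) values$error <- 0
  if (any(values$error < 0)) stop("pcs_dataset: negative uncertainty")
  if (anyDuplicated(paste(values$resno, values$elety)))
    stop("pcs_dataset: duplicate (residue, atom) entries")
  out <- data.frame(resno = as.integer(values$resno),
                    elety = as.character(values$elety),
                    value = as.numeric(values$value),
                    error = as.numeric(values$error),
                    stringsAsFactors = FALSE)
  structure(out, class = c("pcs_dataset", "data.frame"),
            site = site_label, tag = tag_label, metal = metal_label,
            label = paste(site_label, tag_label, metal_label, sep = ":"))
}

dataset_label <- function(d) attr(d, "label")

#' @export
print.pcs_dataset <- function(x, ...) {
  cat(sprintf("pcs_dataset %s: %d shifts, range [%.3f, %.3f] ppm\n",
              attr(x, "label"), nrow(x), min(x$value), max(x$value)))
  invisible(x)
}

#' Read a PCS table in NPC format
#'
#' Four whitespace-separated columns (`residue_number atom_name value
#' error`), `#` comments.
#'
#' @param path input file.
#' @param site_label,tag_label,metal_label dataset labels; see
#'   [pcs_dataset()].
#' @return a [pcs_dataset()].
#' @export
read_npc <- function(path, site_label, tag_label, metal_label) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("resno", "elety", "value", "error"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric"))
  pcs_dataset(site_label, tag_label, metal_label, tab)
}

#' Write a PCS dataset in NPC format
#'
#' @param dataset a [pcs_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_npc <- function(dataset, path) {
  header <- sprintf("# PCS (ppm), site=%s tag=%s metal=%s",
                    attr(dataset, "site"), attr(dataset, "tag"),
                    attr(dataset, "metal"))
  body <- sprintf("%4d %-5s %12.6f %10.6f", dataset$resno, dataset$elety,
                  dataset$value, dataset$error)
  writeLines(c(header, body), path)
  invisible(path)
}

# Join a dataset to structure coordinates; unmatched PCS entries are
# dropped with a logged count (incomplete assignments are the norm).
match_dataset <- function(dataset, model) {
  mkey <- paste(model$resno, model$elety)
  m <- match(paste(dataset$resno, dataset$elety), mkey)
  n_miss <- sum(is.na(m))
  if (n_miss > 0)
    message(sprintf("%s: dropped %d PCS value(s) with no matching atom",
                    dataset_label(dataset), n_miss))
  keep <- !is.na(m)
  list(positions = atom_xyz(model)[m[keep], , drop = FALSE],
       values = dataset$value[keep],
       errors = dataset$error[keep],
       resno = dataset$resno[keep],
       elety = dataset$elety[keep],
       n_dropped = n_miss)
}
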