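# Library screening: score every library molecule with a trained model,
# retain those with relative probability score strictly above the cutoff
# (default 0.7), then optionally filter on externally produced docking
# binding energies (retain strictly below the cutoff, default -10.0
# kcal/mol, sorted most-negative first).

#' Screen a compound library with a trained model
#'
#' Computes descriptors for each molecule (embedding 3D coordinates where
#' missing), imputes remaining masked values, applies the model and retains
#' compounds whose score strictly exceeds the threshold, ranked by
#' descending score. Molecules whose descriptors cannot be computed are
#' excluded and reported in the `failures` attribute.
#'
#' @param model a trained classifier (`rf_model`, `svm_model`, ...).
#' @param mols list of standardized `Molecule` objects.
#' @param threshold retention cutoff on the score (strict `>`).
#' @param registry descriptor registry used at training time.
#' @param medians named vector of training medians for imputation (see
#'   [impute_missing()]); masked descriptors without a median fall back
#'   to 0.
#' @param scaling optional `params` from [standardize_features()], for
#'   models trained on standardized features.
#' @return data.frame of class `screening_hits`: `id`, `smiles`, `score`,
#'   `rank` (1..n without gaps), `energy` (NA until
#'   [filter_by_energy()]).
#' @export
screen_library <- function(model, mols, threshold = 0.7,
                           registry = descriptor_registry(),
                           medians = NULL, scaling = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  if (inherits(mols, "Molecule")) mols <- list(mols)
  if (!length(mols)) return(.empty_hits())
  mols <- lapply(mols, embed_coordinates)
  tab <- suppressWarnings(compute_descriptors(mols, registry))
  failures <- attr(tab, "failures")
  if (!nrow(tab)) {
    out <- .empty_hits(); attr(out, "failures") <- failures; return(out)
  }
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab$id
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      fill <- if (!is.null(medians) && colnames(x)[j] %in% names(medians))
        medians[[colnames(x)[j]]] else 0
      x[miss, j] <- fill
    }
  }
  if (!is.null(scaling)) x <- .apply_scaling(x, scaling)
  pr <- predict(model, x)
  keep <- pr$score > threshold
  pr <- pr[keep, , drop = FALSE]
  o <- order(-pr$score, pr$id)
  smiles <- tryCatch(write_smiles(mols[match(pr$id[o], tab$id)]),
                     error = function(e) rep(NA_character_, sum(keep)))
  out <- data.frame(id = pr$id[o], smiles = unname(smiles),
                    score = pr$score[o],
                    rank = seq_len(sum(keep)), energy = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("screening_hits", "data.frame")
  attr(out, "failures") <- failures
  attr(out, "threshold") <- threshold
  out
}

.empty_hits <- function() {
  out <- data.frame(id = character(), smiles = character(), score = numeric(),
                    rank = integer(), energy = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("screening_hits", "data.frame")
  out
}

#' Load docking binding energies from CSV
#'
#' Expects columns `id` and `energy` (kcal/mol); header optional. Rows with
#' non-numeric energies are skipped with a diagnostic; a duplicated id keeps
#' the last value with a warning.
#'
#' @param path CSV path.
#' @return named numeric vector (id -> energy in kcal/mol).
#' @export
load_energies <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("energy table needs two columns: id, energy")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2]))) &&
      tolower(trimws(raw[1, 1])) %in% c("id", "name", "compound"))
    raw <- raw[-1, , drop = FALSE]
  en <- suppressWarnings(as.numeric(raw[, 2]))
  bad <- is.na(en)
  if (any(bad))
    warning(sum(bad), " energy row(s) skipped (non-numeric): ",
            paste(raw[bad, 1], collapse = ", "))
  ids <- trimws(raw[!bad, 1]); en <- en[!bad]
  if (anyDuplicated(ids)) {
    warning("duplicate id(s) in energy table; last value wins: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; en <- en[keep]
  }
  stats::setNames(en, ids)
}

#' Filter screening hits by docking binding energy
#'
#' Retains hits with an imported binding energy strictly below the cutoff
#' (more negative = stronger predicted binding) and sorts them by ascending
#' energy. Hits without an energy entry are excluded and counted in the
#' `missing_energy` attribute.
#'
#' @param hits a `screening_hits` data.frame.
#' @param energies named vector from [load_energies()].
#' @param cutoff retention cutoff in kcal/mol (strict `<`).
#' @return filtered `screening_hits`, re-ranked by energy.
#' @export
filter_by_energy <- function(hits, energies, cutoff = -10.0) {
  stopifnot(is.finite(cutoff))
  if (!nrow(hits)) return(hits)
  hits$energy <- unname(energies[hits$id])
  missing <- is.na(hits$energy)
  out <- hits[!missing & hits$energy < cutoff, , drop = FALSE]
  out <- out[order(out$energy, out$id), , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screening_hits", "data.frame")
  attr(out, "missing_energy") <- sum(missing)
  out
}

#' Write screening hits to CSV (and optionally SDF)
#'
#' @param hits a `screening_hits` data.frame.
#' @param path CSV output path.
#' @param mols optional molecule list; retained hits are also written as SDF
#'   next to `path`.
#' @return invisibly, the path.
#' @export
write_hits <- function(hits, path, mols = NULL) {
  utils::write.csv(as.data.frame(hits), path, row.names = FALSE, na = "")
  if (!is.null(mols)) {
    ids <- vapply(mols, function(m) m$id, character(1))
    sel <- mols[match(hits$id, ids, nomatch = 0L)]
    if (length(sel)) write_sdf(sel, sub("\\.csv$", ".sdf", path))
  }
  invisible(path)
}

#' Recorded docking-box configuration
#'
#' The receptor grid-box parameters used when exporting retained hits to an
#' external docking program (box 16 x 16 x 16 Angstrom centred at
#' X = 22.599, Y = -2.481, Z = 28.0 on the camptothecin-bound Top1 ternary
#' complex). No docking is executed by this package; the block is exported
#' for users who run one.
#'
#' @return named list of box parameters.
#' @export
docking_box_config <- function() {
  list(size_x = 16, size_y = 16, size_z = 16,
       center_x = 22.599, center_y = -2.481, center_z = 28.0,
       receptor_pdb = "1T8I", units = "angstrom")
}
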