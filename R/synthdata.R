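# Fixture generation: synthetic two-class descriptor datasets with
# controlled separation, and combinatorial analog libraries around a
# scaffold. These stand in for the proprietary inhibitor/non-inhibitor
# collections, giving every pipeline stage a testable input with a known
# ground truth (the Gaussian model has Bayes error pnorm(-d/2) for a single
# informative feature at unit variance).

#' Specification for a synthetic two-class dataset
#'
#' @param n_per_class compounds per class (>= 2).
#' @param p feature count.
#' @param d class-mean separation on the informative features, in pooled-sd
#'   units.
#' @param informative number of features carrying the separation (1..p).
#' @param covariance `"identity"` or `"equicorrelated"`.
#' @param rho common correlation when equicorrelated.
#' @param heavy_tails if TRUE, draw from a scaled t (df = 5) instead of a
#'   normal, for robustness checks.
#' @param seed RNG seed recorded alongside the other parameters.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 500L, p = 10L, d = 4, informative = 1L,
                       covariance = c("identity", "equicorrelated"),
                       rho = 0.3, heavy_tails = FALSE, seed = 1L) {
  covariance <- match.arg(covariance)
  stopifnot(n_per_class >= 2L, p >= 1L, informative >= 1L, informative <= p)
  structure(list(n_per_class = as.integer(n_per_class), p = as.integer(p),
                 d = d, informative = as.integer(informative),
                 covariance = covariance, rho = rho,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a labeled two-class Gaussian dataset
#'
#' Class -1 is centred at the origin; class +1 differs by `d` (in pooled-sd
#' units) on exactly the first `informative` features. All generator
#' parameters are recorded in the `spec` attribute of the result.
#'
#' @param spec a `synth_spec`.
#' @return a `labeled_dataset` with `2 * n_per_class` rows.
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class; p <- spec$p
  draw <- function(nr) {
    z <- matrix(rnorm(nr * p), nr, p)
    if (spec$heavy_tails) {
      df <- 5
      z <- matrix(stats::rt(nr * p, df) / sqrt(df / (df - 2)), nr, p)
    }
    if (spec$covariance == "equicorrelated") {
      S <- matrix(spec$rho, p, p); diag(S) <- 1
      z <- z %*% chol(S)
    }
    z
  }
  xm <- draw(n); xp <- draw(n)
  xp[, seq_len(spec$informative)] <- xp[, seq_len(spec$informative)] + spec$d
  x <- rbind(xm, xp)
  colnames(x) <- paste0("f", seq_len(p))
  d <- labeled_dataset(x, c(rep(-1L, n), rep(1L, n)))
  attr(d, "spec") <- spec
  d
}

#' Enumerate a substituted analog library around a scaffold
#'
#' Emulates the scaffold redundancy of real screening libraries: the
#' scaffold SMILES carries a literal `{R}` attachment marker, replaced in
#' turn by each substituent fragment (an empty substituent gives the bare
#' scaffold). Invalid combinations are skipped with a diagnostic; duplicate
#' structures (by canonical SMILES) are removed.
#'
#' @param scaffold SMILES containing one `{R}` marker.
#' @param substituents character vector of substituent SMILES fragments.
#' @param n maximum number of analogs returned.
#' @return list of standardized `Molecule` objects (attribute `failures` as
#'   in [read_smiles()]).
#' @export
gen_library <- function(scaffold, substituents, n = Inf) {
  if (!grepl("{R}", scaffold, fixed = TRUE))
    stop("scaffold must contain an {R} attachment marker")
  if (!length(substituents)) substituents <- ""
  smi <- vapply(substituents, function(s)
    sub("{R}", s, scaffold, fixed = TRUE), character(1))
  ids <- sprintf("analog%03d", seq_along(smi))
  mols <- suppressWarnings(read_smiles(smi, ids))
  fails <- attr(mols, "failures")
  mols <- standardize(mols)
  can <- tryCatch(write_smiles(mols), error = function(e)
    vapply(mols, .fragment_key, character(1)))
  keep <- !duplicated(unname(can))
  out <- mols[keep]
  if (length(out) > n) out <- out[seq_len(n)]
  attr(out, "failures") <- fails
  out
}
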