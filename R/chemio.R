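# Molecule input/output and standardization.
#
# Parsing of SMILES and V2000 SDF is delegated to ChemmineR/ChemmineOB
# (OpenBabel); the connection tables they return are kekulized, so aromatic
# rings are re-perceived here with an explicit Hueckel-style rule that the
# descriptor code can rely on.

# SDF atom-line charge codes (field 6 of a V2000 atom line)
.CHG_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
               `5` = -1L, `6` = -2L, `7` = -3L)

# smallest allowed valence >= bond-order sum, given formal charge.
# Elements outside the organic subset (counter-ion metals etc.) get no
# implicit hydrogens; they survive parsing so that standardize() can strip
# them, and heavy_graph() rejects them if they reach descriptor code.
.effective_valence <- function(el, q, bondsum) {
  if (el == "C") return(4L - abs(q))
  allowed <- switch(el,
    N = c(3L, 5L), P = c(3L, 5L), S = c(2L, 4L, 6L),
    O = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L,
    return(0L))
  allowed <- allowed + q
  ok <- allowed[allowed >= bondsum]
  if (length(ok)) min(ok) else max(allowed)
}

# ---- simple-cycle enumeration (sizes 3..maxlen) --------------------------
# Each simple cycle is reported once, as a vertex vector starting at its
# smallest vertex, oriented toward the smaller of its two neighbours.
.simple_cycles <- function(adj, n, maxlen = 7L) {
  cycles <- list()
  for (s in seq_len(n)) {
    # DFS restricted to vertices > s except for closing back to s
    path <- integer(maxlen)
    walk <- function(v, depth, inpath) {
      for (w in adj[[v]]) {
        if (w == s && depth >= 3L) {
          cyc <- path[seq_len(depth)]
          if (cyc[2] < cyc[depth])  # canonical orientation: one of two only
            cycles[[length(cycles) + 1L]] <<- cyc
        } else if (w > s && !inpath[w] && depth < maxlen) {
          path[depth + 1L] <<- w
          inpath[w] <- TRUE
          walk(w, depth + 1L, inpath)
          inpath[w] <- FALSE
        }
      }
    }
    inpath <- rep.int(FALSE, n)
    path[1] <- s; inpath[s] <- TRUE
    walk(s, 1L, inpath)
  }
  cycles
}

# ---- aromaticity ---------------------------------------------------------
# A simple ring of size 5-7 is aromatic when (i) all members are C/N/O/S,
# (ii) no member is a saturated carbon (a carbon with neither a double nor
# triple bond), and (iii) the Hueckel count over the ring is 4k+2, where an
# atom with an in-ring double bond contributes 1 pi electron, a heteroatom
# without one contributes its lone pair (2), and a carbon whose only double
# bond points out of the ring (e.g. quinone C=O) contributes 0.
.perceive_aromaticity <- function(atoms, bonds) {
  n <- nrow(atoms)
  atoms$aromatic <- rep.int(FALSE, n)
  if (nrow(bonds)) bonds$aromatic <- rep.int(FALSE, nrow(bonds)) else {
    return(list(atoms = atoms, bonds = bonds))
  }
  adj <- vector("list", n); for (i in seq_len(n)) adj[[i]] <- integer()
  bkey <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    assign(paste(a, b), k, envir = bkey)
  }
  bond_at <- function(a, b) get(paste(min(a, b), max(a, b)), envir = bkey)
  has_multiple <- rep.int(FALSE, n)  # any double/triple bond on atom
  for (k in seq_len(nrow(bonds))) if (bonds$order[k] >= 2L) {
    has_multiple[bonds$a1[k]] <- TRUE; has_multiple[bonds$a2[k]] <- TRUE
  }
  cycles <- .simple_cycles(adj, n, maxlen = 7L)
  for (cyc in cycles) {
    len <- length(cyc)
    if (len < 5L || len > 7L) next
    el <- atoms$element[cyc]
    if (!all(el %in% c("C", "N", "O", "S"))) next
    ring_bonds <- vapply(seq_len(len), function(i)
      bond_at(cyc[i], cyc[if (i == len) 1L else i + 1L]), integer(1))
    in_ring_double <- rep.int(FALSE, len)
    for (i in seq_len(len)) {
      k1 <- ring_bonds[if (i == 1L) len else i - 1L]; k2 <- ring_bonds[i]
      in_ring_double[i] <- bonds$order[k1] == 2L || bonds$order[k2] == 2L
    }
    pi_e <- 0L; ok <- TRUE
    for (i in seq_len(len)) {
      if (in_ring_double[i]) pi_e <- pi_e + 1L
      else if (el[i] %in% c("N", "O", "S")) pi_e <- pi_e + 2L
      else if (has_multiple[cyc[i]]) pi_e <- pi_e + 0L  # exocyclic double bond
      else { ok <- FALSE; break }                        # saturated carbon
    }
    if (ok && pi_e %% 4L == 2L) {
      atoms$aromatic[cyc] <- TRUE
      bonds$aromatic[ring_bonds] <- TRUE
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# ---- conversion from a ChemmineR SDF record ------------------------------
# Folds explicit hydrogens into heavy-atom nH counts, fills implicit
# hydrogens from valence rules, applies charge overrides (M CHG supersedes
# atom-line codes), and perceives aromaticity.
.from_sdf_record <- function(ab, bb, id, source, chg_override = NULL,
                             keep_coords = FALSE) {
  el <- sub("_.*$", "", rownames(ab))
  n <- length(el)
  q <- rep.int(0L, n)
  chg_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else if (ncol(ab) >= 6) ab[, 6]
  if (!is.null(chg_col)) {
    code <- as.character(as.integer(chg_col))
    q <- unname(.CHG_CODE[ifelse(code %in% names(.CHG_CODE), code, "0")])
  }
  if (!is.null(chg_override) && nrow(chg_override)) {
    q[] <- 0L  # per V2000, M CHG resets all atom-line charges
    q[chg_override$atom] <- chg_override$charge
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    b1 <- b2 <- integer(); bo <- integer(); arom_in <- logical()
  } else {
    b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
    arom_in <- bo == 4L           # V2000 'aromatic' bond type
    bo[arom_in] <- 1L
  }
  bondsum <- rep.int(0, n); expH <- rep.int(0L, n)
  heavy <- el != "H"
  for (k in seq_along(b1)) {
    ord <- if (arom_in[k]) 1.5 else bo[k]  # aromatic bonds count 1.5
    bondsum[b1[k]] <- bondsum[b1[k]] + ord
    bondsum[b2[k]] <- bondsum[b2[k]] + ord
  }
  bondsum <- as.integer(ceiling(bondsum))
  # fold explicit hydrogens into neighbours
  for (k in seq_along(b1)) {
    if (!heavy[b1[k]] && heavy[b2[k]]) expH[b2[k]] <- expH[b2[k]] + 1L
    if (!heavy[b2[k]] && heavy[b1[k]]) expH[b1[k]] <- expH[b1[k]] + 1L
  }
  if (!any(heavy)) stop("molecule has no heavy atoms")
  newidx <- cumsum(heavy); newidx[!heavy] <- NA_integer_
  keep_b <- heavy[b1] & heavy[b2]
  atoms <- data.frame(element = el[heavy], charge = q[heavy],
                      nH = expH[heavy], aromatic = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(atoms))) {
    j <- which(heavy)[i]
    v <- .effective_valence(atoms$element[i], atoms$charge[i], bondsum[j])
    atoms$nH[i] <- expH[j] + max(0L, v - bondsum[j])
  }
  bonds <- data.frame(a1 = newidx[b1[keep_b]], a2 = newidx[b2[keep_b]],
                      order = bo[keep_b], aromatic = FALSE)
  if (keep_coords) {
    atoms$x <- ab[heavy, 1]; atoms$y <- ab[heavy, 2]; atoms$z <- ab[heavy, 3]
  }
  p <- .perceive_aromaticity(atoms, bonds)
  # honour explicit aromatic bond types from the input as well
  if (any(arom_in[keep_b])) {
    p$bonds$aromatic <- p$bonds$aromatic | arom_in[keep_b]
    aridx <- unique(c(p$bonds$a1[p$bonds$aromatic], p$bonds$a2[p$bonds$aromatic]))
    p$atoms$aromatic[aridx] <- TRUE
  }
  molecule(id, p$atoms, p$bonds, source = source)
}

#' Read molecules from SMILES
#'
#' Parses one or more SMILES strings into [molecule()] objects with aromatic
#' perception applied and attached-hydrogen counts filled from valence rules.
#' Records that fail to parse are rejected whole (never a partial molecule):
#' they are skipped, counted, and reported in the `failures` attribute of the
#' result and via a warning.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional character vector of identifiers (defaults to
#'   `mol1`, `mol2`, ...).
#' @return list of `Molecule` objects; attribute `failures` is a data.frame
#'   with columns `id` and `reason` for rejected records.
#' @examples
#' mols <- read_smiles(c("CCO", "c1ccccc1"), ids = c("ethanol", "benzene"))
#' @export
read_smiles <- function(smiles, ids = NULL) {
  smiles <- as.character(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  out <- list(); fail_id <- character(); fail_why <- character()
  for (i in seq_along(smiles)) {
    m <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], ids[i])))
      if (!suppressWarnings(ChemmineR::validSDF(sdf))) stop("invalid record")
      .from_sdf_record(ChemmineR::atomblock(sdf[[1]]), ChemmineR::bondblock(sdf[[1]]),
                       id = ids[i], source = "smiles")
    }, error = function(e) e)
    if (inherits(m, "error"))  # ChemmineR cannot represent single-atom records
      m <- tryCatch(.single_atom_fallback(smiles[i], ids[i]), error = function(e) m)
    if (inherits(m, "error")) {
      fail_id <- c(fail_id, ids[i])
      fail_why <- c(fail_why, conditionMessage(m))
    } else out[[length(out) + 1L]] <- m
  }
  attr(out, "failures") <- data.frame(id = fail_id, reason = fail_why,
                                      stringsAsFactors = FALSE)
  if (length(fail_id))
    warning(length(fail_id), " SMILES record(s) rejected: ",
            paste(fail_id, collapse = ", "))
  out
}

# Fallback for single-heavy-atom SMILES, which ChemmineR's SDF container
# cannot hold: convert via OpenBabel and read the lone V2000 atom line.
.single_atom_fallback <- function(smi, id) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", source = paste(smi, id))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3)); nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms != 1L || nbonds != 0L) stop("not a single-atom record")
  f <- strsplit(trimws(lines[5]), "\\s+")[[1]]
  el <- f[4]
  q <- unname(.CHG_CODE[as.character(as.integer(f[5 + 1]))])
  if (is.na(q)) q <- 0L
  for (ln in grep("^M  CHG", lines, value = TRUE))
    q <- as.integer(strsplit(trimws(sub("^M  CHG  1", "", ln)), "\\s+")[[1]][2])
  nH <- max(0L, .effective_valence(el, q, 0L))
  molecule(id, data.frame(element = el, charge = q, nH = nH, aromatic = FALSE,
                          stringsAsFactors = FALSE),
           data.frame(), source = "smiles")
}

# scan raw SDF text for per-record M CHG overrides and 2D/3D dimension flags
.sdf_raw_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(1L, head(lines, -1) == "$$$$")))
  lapply(recs, function(r) {
    if (length(r) < 4L) return(NULL)
    chg <- NULL
    for (ln in grep("^M  CHG", r, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      chg <- rbind(chg, data.frame(atom = f[seq(2, 2 * k, 2)],
                                   charge = f[seq(3, 2 * k + 1, 2)]))
    }
    list(chg = chg, is3d = grepl("3D", r[2], fixed = TRUE))
  })
}

#' Read molecules from an SDF file
#'
#' Reads a V2000 SDF; each record becomes one `Molecule`, in file order. 3D
#' coordinates are preserved when the record declares them (dimension flag
#' `3D` in the header, or a nonzero z column). Malformed records are skipped
#' with a diagnostic and counted in the `failures` attribute.
#'
#' @param path path to an SDF file.
#' @return list of `Molecule` objects with a `failures` attribute as in
#'   [read_smiles()].
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    return(structure(list(), failures = data.frame(id = character(),
                                                   reason = character())))
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  valid <- ChemmineR::validSDF(sdfs)
  meta <- .sdf_raw_meta(path)
  out <- list(); fail_id <- character(); fail_why <- character()
  for (i in seq_along(sdfs)) {
    rid <- ChemmineR::sdfid(sdfs[i])
    if (!nzchar(rid) || is.na(rid)) rid <- paste0("sdf_record_", i)
    if (!valid[i]) {
      fail_id <- c(fail_id, rid); fail_why <- c(fail_why, "malformed SDF record")
      next
    }
    mi <- if (i <= length(meta)) meta[[i]] else NULL
    ab <- ChemmineR::atomblock(sdfs[[i]])
    is3d <- (!is.null(mi) && isTRUE(mi$is3d)) || any(abs(ab[, 3]) > 1e-4)
    m <- tryCatch(
      .from_sdf_record(ab, ChemmineR::bondblock(sdfs[[i]]), id = rid,
                       source = "sdf", chg_override = if (!is.null(mi)) mi$chg,
                       keep_coords = is3d),
      error = function(e) e)
    if (inherits(m, "error")) {
      fail_id <- c(fail_id, rid); fail_why <- c(fail_why, conditionMessage(m))
    } else out[[length(out) + 1L]] <- m
  }
  attr(out, "failures") <- data.frame(id = fail_id, reason = fail_why,
                                      stringsAsFactors = FALSE)
  if (length(fail_id))
    warning(length(fail_id), " SDF record(s) skipped: ",
            paste(fail_id, collapse = ", "))
  out
}

# ---- writers -------------------------------------------------------------

.mol_to_v2000 <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  xyz <- cbind(ifelse(is.na(a$x), 0, a$x), ifelse(is.na(a$y), 0, a$y),
               ifelse(is.na(a$z), 0, a$z))
  dim_flag <- if (has_coordinates(mol)) "3D" else "2D"
  lines <- c(mol$id, paste0("  topscreen          ", dim_flag), "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)))
  for (i in seq_len(nrow(a)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[i, 1], xyz[i, 2], xyz[i, 3], a$element[i]))
  for (k in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$a1[k], b$a2[k], b$order[k]))
  chg <- which(a$charge != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, a$charge[chg]), collapse = "")))
  # re-expose suppressed hydrogens is not needed for round-trip of the
  # heavy-atom view; nH counts are restored from valence on re-read
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF file (V2000)
#'
#' @param mols a `Molecule` or list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  txt <- unlist(lapply(mols, .mol_to_v2000))
  writeLines(txt, path)
  invisible(path)
}

#' Canonical SMILES for molecules
#'
#' Round-trips through OpenBabel's canonical SMILES writer.
#'
#' @param mols a `Molecule` or list of them.
#' @return named character vector of canonical SMILES.
#' @export
write_smiles <- function(mols) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  tf <- tempfile(fileext = ".sdf"); on.exit(unlink(tf))
  write_sdf(mols, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  smi <- ChemmineR::sdf2smiles(sdfs)
  out <- as.character(smi)
  names(out) <- vapply(mols, function(m) m$id, character(1))
  out
}

# ---- standardization -----------------------------------------------------

.extract_fragment <- function(mol, keep) {
  idx <- which(keep); newidx <- match(seq_len(nrow(mol$atoms)), idx)
  kb <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
  bonds <- mol$bonds[kb, , drop = FALSE]
  bonds$a1 <- newidx[bonds$a1]; bonds$a2 <- newidx[bonds$a2]
  molecule(mol$id, mol$atoms[idx, , drop = FALSE], bonds, source = mol$source)
}

#' Standardize a molecule
#'
#' Applies the preprocessing used before descriptor calculation: keep only
#' the largest connected fragment (counter ions and salts are dropped; ties
#' broken by the lexicographically smaller canonical SMILES), neutralize
#' formal charges where adding or removing one proton suffices
#' (carboxylates/alkoxides/thiolates/amides gain an H; protonated amines
#' lose one; quaternary centres and zwitterionic pairs that cannot be fixed
#' by protonation are left intact), and re-perceive aromaticity.
#' Idempotent on already-clean input.
#'
#' @param mol a `Molecule`, or a list of them (processed element-wise).
#' @return standardized `Molecule` (or list).
#' @export
standardize <- function(mol) {
  if (is.list(mol) && !inherits(mol, "Molecule"))
    return(lapply(mol, standardize))
  comp <- .components(nrow(mol$atoms), as.matrix(mol$bonds[, c("a1", "a2")]))
  sizes <- table(comp)
  if (length(sizes) > 1L) {
    best <- as.integer(names(sizes)[sizes == max(sizes)])
    if (length(best) > 1L) {
      frags <- lapply(best, function(cc) .extract_fragment(mol, comp == cc))
      keys <- tryCatch(unname(write_smiles(frags)),
                       error = function(e) vapply(frags, .fragment_key, character(1)))
      best <- best[order(keys)][1]
    }
    mol <- .extract_fragment(mol, comp == best[1])
  }
  a <- mol$atoms
  for (i in seq_len(nrow(a))) {
    if (a$charge[i] == -1L && a$element[i] %in% c("O", "S", "N")) {
      a$charge[i] <- 0L; a$nH[i] <- a$nH[i] + 1L
    } else if (a$charge[i] == 1L && a$element[i] %in% c("N", "P") && a$nH[i] >= 1L) {
      a$charge[i] <- 0L; a$nH[i] <- a$nH[i] - 1L
    }
  }
  p <- .perceive_aromaticity(a, mol$bonds)
  molecule(mol$id, p$atoms, p$bonds, source = mol$source)
}

# deterministic fallback fragment ordering key (element/degree/nH multiset)
.fragment_key <- function(m) {
  g <- heavy_graph(m)
  paste(sort(paste(g$element, g$degree, g$nH, sep = ":")), collapse = "|")
}

#' Deterministic 3D embedding from the molecular graph
#'
#' Generates 3D coordinates for a molecule that lacks them, by classical
#' multidimensional scaling of the topological distance matrix scaled to a
#' typical bond length of 1.52 Angstrom. The construction involves no random
#' numbers, so repeated calls give identical geometry. The embedding is a
#' coarse surrogate geometry sufficient for the grid-based geometric
#' descriptors; it is not a force-field conformation.
#'
#' @param mol a standardized `Molecule`.
#' @param bond_length scale in Angstrom applied to graph distances.
#' @return the `Molecule` with coordinates filled in.
#' @export
embed_coordinates <- function(mol, bond_length = 1.52) {
  if (has_coordinates(mol)) return(mol)
  g <- heavy_graph(mol)
  n <- g$n
  if (n == 1L) {
    mol$atoms$x <- mol$atoms$y <- mol$atoms$z <- 0
    return(mol)
  }
  D <- .graph_distances(g) * bond_length
  xyz <- suppressWarnings(stats::cmdscale(D, k = min(3L, n - 1L)))
  if (ncol(xyz) < 3L) xyz <- cbind(xyz, matrix(0, n, 3L - ncol(xyz)))
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
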