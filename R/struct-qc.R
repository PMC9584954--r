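#' CAPRI thresholds
#'
#' Interface-RMSD class boundaries and the interface-detection cutoff.
#' Half-open binning assigns each boundary to the lower-quality class:
#' `[0, high)` = high, `[high, medium)` = medium, `[medium, acceptable)` =
#' acceptable, `[acceptable, Inf)` = incorrect.
#'
#' @param high,medium,acceptable Class boundaries in Angstrom (strictly
#'   increasing).
#' @param interface_cutoff Heavy-atom intermolecular distance (Angstrom)
#'   defining interface residues; inclusive.
#' @return List of class `capri_thresholds`.
#' @export
capri_thresholds <- function(high = 1.0, medium = 2.0, acceptable = 4.0,
                             interface_cutoff = 8.0) {
  if (!(high < medium && medium < acceptable)) {
    stop("thresholds must be strictly increasing")
  }
  stopifnot(interface_cutoff > 0)
  structure(
    list(high = high, medium = medium, acceptable = acceptable,
         interface_cutoff = interface_cutoff),
    class = "capri_thresholds"
  )
}

#' Read a structure from PDB text or file
#'
#' Parses ATOM/HETATM records (via bio3d) into a flat atom table.
#' Coordinate fields are pre-validated so a malformed record is reported
#' with its line number. Hydrogen and deuterium atoms are flagged
#' non-heavy; for alternate locations the highest-occupancy conformer is
#' kept.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines.
#' @return Data frame of class `pdb_structure` with columns `record`,
#'   `chain`, `resno`, `resid`, `elety` (atom name), `element`,
#'   `x`, `y`, `z`, `occupancy`, `is_heavy`.
#' @export
read_structure <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  for (i in which(is_atom)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      stop("malformed coordinate field at line ", i)
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  element <- toupper(trimws(a$elesy))
  no_elem <- is.na(element) | element == ""
  # fall back on the atom-name convention when the element column is blank
  element[no_elem] <- toupper(substr(trimws(a$elety[no_elem]), 1, 1))
  s <- data.frame(
    record = a$type, chain = a$chain, resno = a$resno, resid = a$resid,
    elety = a$elety, element = element,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    is_heavy = !(element %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  # altloc resolution: highest occupancy per (chain, residue, atom name)
  key <- paste(s$chain, s$resno, s$elety, sep = "\r")
  if (anyDuplicated(key)) {
    s <- s[order(key, -s$occupancy), , drop = FALSE]
    s <- s[!duplicated(paste(s$chain, s$resno, s$elety, sep = "\r")), ,
           drop = FALSE]
    s <- s[order(s$chain, s$resno), , drop = FALSE]
  }
  rownames(s) <- NULL
  class(s) <- c("pdb_structure", "data.frame")
  s
}

# squared Euclidean cross-distances between two coordinate matrices
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

.coords <- function(s) as.matrix(s[, c("x", "y", "z")])

#' Interface residues between two chain groups
#'
#' A residue belongs to the interface iff at least one of its heavy atoms
#' lies within `cutoff` (inclusive) of a heavy atom of the other group.
#'
#' @param s A `pdb_structure`.
#' @param group1,group2 Disjoint, nonempty character vectors of chain ids.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return Data frame with columns `group` (1 or 2), `chain`, `resno`,
#'   sorted by group, chain, residue number.
#' @export
interface_residues <- function(s, group1, group2, cutoff = 8.0) {
  stopifnot(inherits(s, "pdb_structure"), cutoff > 0)
  if (length(group1) == 0L || length(group2) == 0L) {
    stop("both chain groups must be nonempty")
  }
  if (length(intersect(group1, group2)) > 0L) {
    stop("chain groups must be disjoint")
  }
  a1 <- s[s$chain %in% group1 & s$is_heavy, , drop = FALSE]
  a2 <- s[s$chain %in% group2 & s$is_heavy, , drop = FALSE]
  if (nrow(a1) == 0L || nrow(a2) == 0L) {
    stop("a chain group matched no heavy atoms")
  }
  d2 <- .cross_dist2(.coords(a1), .coords(a2))
  close <- d2 <= cutoff^2
  pick <- function(atoms, in_iface, grp) {
    r <- unique(atoms[in_iface, c("chain", "resno"), drop = FALSE])
    if (nrow(r) == 0L) {
      return(data.frame(group = integer(), chain = character(),
                        resno = integer(), stringsAsFactors = FALSE))
    }
    r <- r[order(r$chain, r$resno), , drop = FALSE]
    data.frame(group = grp, chain = r$chain, resno = r$resno,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(a1, apply(close, 1L, any), 1L),
               pick(a2, apply(close, 2L, any), 2L))
  rownames(out) <- NULL
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform mapping `coords_model` onto
#' `coords_reference`, computed from the SVD of the covariance matrix
#' with reflection correction, so the returned rotation is always proper
#' (determinant +1).
#'
#' @param coords_model,coords_reference n x 3 matrices of paired
#'   coordinates, n >= 3 and not collinear.
#' @return List of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3; the fit is
#'   `rotation %*% x + translation`), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coords_model, coords_reference) {
  p <- as.matrix(coords_model)
  q <- as.matrix(coords_reference)
  if (nrow(p) != nrow(q) || ncol(p) != 3L || ncol(q) != 3L) {
    stop("coordinate sets must be paired n x 3 matrices")
  }
  if (nrow(p) < 3L) stop("superposition needs >= 3 paired atoms")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  h <- crossprod(pc, qc)
  sv <- svd(h)
  if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1e-12)) {
    stop("degenerate (collinear) coordinate set")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- tcrossprod(pc, rot)
  rmsd <- sqrt(mean(rowSums((fitted - qc)^2)))
  structure(
    list(rotation = rot,
         translation = as.numeric(cq - rot %*% cp),
         rmsd = rmsd),
    class = "superposition"
  )
}

#' Interface RMSD of a docking model
#'
#' CAPRI-style I_rmsd: interface residues are detected on the REFERENCE
#' complex at `cutoff` Angstrom; the heavy atoms of those residues are
#' matched between model and reference by (chain, residue number, atom
#' name), superposed with [kabsch_superpose()], and their RMSD after
#' superposition is returned. Atoms present in only one structure are
#' dropped with a warning.
#'
#' @param model,reference `pdb_structure` objects sharing chain/residue/
#'   atom naming over the interface.
#' @param group1,group2 The two docking partner chain groups.
#' @param cutoff Interface cutoff in Angstrom (default 8).
#' @return I_rmsd in Angstrom, with attributes `n_atoms` (matched heavy
#'   atoms) and `n_residues` (interface residues).
#' @export
irmsd <- function(model, reference, group1, group2, cutoff = 8.0) {
  iface <- interface_residues(reference, group1, group2, cutoff)
  ikey <- paste(iface$chain, iface$resno, sep = "\r")
  sel <- function(s) {
    a <- s[s$is_heavy & paste(s$chain, s$resno, sep = "\r") %in% ikey, ,
           drop = FALSE]
    a$akey <- paste(a$chain, a$resno, a$elety, sep = "\r")
    a
  }
  am <- sel(model); ar <- sel(reference)
  common <- intersect(am$akey, ar$akey)
  dropped <- (nrow(am) - length(common)) + (nrow(ar) - length(common))
  if (dropped > 0L) {
    warning(dropped, " unmatched interface atom(s) dropped")
  }
  if (length(common) < 3L) {
    stop("fewer than 3 matched interface heavy atoms")
  }
  mm <- .coords(am[match(common, am$akey), , drop = FALSE])
  mr <- .coords(ar[match(common, ar$akey), , drop = FALSE])
  fit <- kabsch_superpose(mm, mr)
  structure(fit$rmsd, n_atoms = length(common),
            n_residues = nrow(iface))
}

#' CAPRI quality class of an interface RMSD
#'
#' @param i_rmsd Nonnegative I_rmsd value(s) in Angstrom.
#' @param thresholds A [capri_thresholds()].
#' @return Character vector in `{high, medium, acceptable, incorrect}`.
#' @export
#' @examples
#' capri_quality(c(1.848, 5.869))  # "medium" "incorrect"
capri_quality <- function(i_rmsd, thresholds = capri_thresholds()) {
  if (any(i_rmsd < 0)) stop("I_rmsd must be nonnegative")
  as.character(cut(
    i_rmsd,
    breaks = c(-Inf, thresholds$high, thresholds$medium,
               thresholds$acceptable, Inf),
    labels = c("high", "medium", "acceptable", "incorrect"),
    right = FALSE
  ))
}

#' Protein residues surrounding a bound ligand
#'
#' Lists the protein residues with any heavy atom within `cutoff`
#' (inclusive) of any heavy atom of the selected ligand, sorted by chain
#' then residue number — e.g. the amino acids within 8 Angstrom of the
#' F430 cofactor in a docking model.
#'
#' @param s A `pdb_structure`.
#' @param ligand_resid Residue name of the ligand (HETATM group), e.g.
#'   `"F43"`.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return Data frame with columns `chain`, `resno`, `resid`.
#' @export
ligand_proximal_residues <- function(s, ligand_resid, cutoff = 8.0) {
  stopifnot(inherits(s, "pdb_structure"), cutoff > 0)
  lig <- s[s$resid == ligand_resid & s$is_heavy, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop("ligand selector '", ligand_resid, "' matched no heavy atoms")
  }
  prot <- s[s$resid != ligand_resid & s$is_heavy, , drop = FALSE]
  d2 <- .cross_dist2(.coords(prot), .coords(lig))
  near <- apply(d2 <= cutoff^2, 1L, any)
  r <- unique(prot[near, c("chain", "resno", "resid"), drop = FALSE])
  r <- r[order(r$chain, r$resno), , drop = FALSE]
  rownames(r) <- NULL
  r
}
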