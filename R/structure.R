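#' Kyte-Doolittle hydropathy indices
#'
#' @return Named numeric vector of hydropathy values for the 20 standard
#'   amino acids (one-letter codes).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Classify residues as hydrophobic or hydrophilic
#'
#' A residue is hydrophobic when its Kyte-Doolittle hydropathy index is
#' strictly positive (A, C, F, I, L, M, V), hydrophilic otherwise.
#'
#' @param sequence Character vector of one-letter codes, or a single string.
#' @return Logical vector, `TRUE` for hydrophobic residues.
#' @export
classify_hydrophobicity <- function(sequence) {
  aa <- if (length(sequence) == 1 && nchar(sequence) > 1)
    strsplit(sequence, "")[[1]] else as.character(sequence)
  kd <- kyte_doolittle()
  bad <- setdiff(unique(aa), names(kd))
  if (length(bad) > 0)
    stop("nonstandard residue code(s): ", paste(bad, collapse = ", "))
  unname(kd[aa] > 0)
}

# Tsai-style heavy-atom van der Waals radius from element and PDB atom name.
# sp3 carbons 1.88, sp2 CH 1.76, sp2 without H 1.61, N 1.64, carbonyl /
# carboxyl / amide O 1.42, hydroxyl O 1.46, S and Se 1.77.
.atom_radius <- function(elem, atom) {
  sp2_noh <- c("C", "CG.ASP", "CG.ASN", "CD.GLU", "CD.GLN", "CZ.ARG",
               "CG.PHE", "CG.TYR", "CZ.TYR", "CG.TRP", "CD2.TRP", "CE2.TRP",
               "CG.HIS")
  sp2_h <- c("CD1.PHE", "CD2.PHE", "CE1.PHE", "CE2.PHE", "CZ.PHE",
             "CD1.TYR", "CD2.TYR", "CE1.TYR", "CE2.TYR",
             "CD1.TRP", "CE3.TRP", "CZ2.TRP", "CZ3.TRP", "CH2.TRP",
             "CD2.HIS", "CE1.HIS")
  hydroxyl_o <- c("OG", "OG1", "OH")
  r <- rep(NA_real_, length(elem))
  r[elem == "N"] <- 1.64
  r[elem %in% c("S", "SE")] <- 1.77
  r[elem == "O"] <- ifelse(sub("\\..*", "", atom[elem == "O"]) %in% hydroxyl_o,
                           1.46, 1.42)
  isC <- elem == "C"
  r[isC] <- ifelse(atom[isC] %in% sp2_noh | sub("\\..*", "", atom[isC]) == "C",
                   1.61,
                   ifelse(atom[isC] %in% sp2_h, 1.76, 1.88))
  r
}

#' Parse a membrane-protein structure from PDB text
#'
#' Reads ATOM records for one chain, drops hydrogens, waters and all other
#' heteroatoms except selenomethionine (mapped to MET), and resolves alternate
#' locations to the highest-occupancy conformer. The structure is assumed to
#' be pre-oriented with the membrane normal along z.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a string containing
#'   newlines or a character vector of record lines).
#' @param chain Chain identifier; `NULL` takes the first chain present.
#' @return An object of class `atomistic_structure`: a list with `atoms`
#'   (tibble: residue, resno, res_name, atom, elem, x, y, z) and `sequence`
#'   (one-letter codes). Residue indices are renumbered contiguously; gaps in
#'   the author numbering are kept as a `gaps` attribute and announced with a
#'   warning.
#' @export
parse_structure <- function(pdb, chain = NULL) {
  if (length(pdb) > 1 || grepl("\n", pdb)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  } else {
    path <- pdb
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- tibble::as_tibble(p$atom)
  at$res_name <- trimws(at$resid)
  # selenomethionine comes in as HETATM; keep it as MET
  at$type[at$res_name == "MSE"] <- "ATOM"
  at$res_name[at$res_name == "MSE"] <- "MET"
  at$elesy[at$res_name == "MET" & trimws(at$elety) == "SE"] <- "SE"
  at <- at[at$type == "ATOM" & !(at$res_name %in% c("HOH", "WAT", "DOD")), ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, ]
  if (nrow(at) == 0) stop("no ATOM records for chain ", chain)
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1)
  at$elem <- elem
  at <- at[!(at$elem %in% c("H", "D")), ]
  # alternate locations: keep the highest-occupancy conformer per atom
  at$alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  at <- at |>
    dplyr::group_by(.data$resno, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$resno, .data$eleno)
  resno <- sort(unique(at$resno))
  if (any(diff(resno) > 1)) {
    gaps <- resno[which(diff(resno) > 1)]
    warning("chain has ", length(gaps), " numbering gap(s) after residue(s) ",
            paste(utils::head(gaps, 5), collapse = ", "),
            "; beads renumbered contiguously")
  } else {
    gaps <- integer()
  }
  idx <- match(at$resno, resno)
  atoms <- tibble::tibble(
    residue = idx, resno = at$resno, res_name = at$res_name,
    atom = trimws(at$elety), elem = at$elem,
    x = at$x, y = at$y, z = at$z)
  seq3 <- atoms$res_name[!duplicated(atoms$residue)]
  sequence <- bio3d::aa321(seq3)
  structure(list(atoms = atoms, sequence = sequence),
            class = "atomistic_structure", gaps = gaps)
}

#' @export
print.atomistic_structure <- function(x, ...) {
  cat("atomistic_structure:", max(x$atoms$residue), "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Build a C-alpha bead chain from an atomistic structure
#'
#' One bead per residue, centred on the C-alpha position, in sequence order.
#'
#' @param structure An `atomistic_structure` from [parse_structure()].
#' @return A `bead_chain` tibble (residue, aa, x, y, z) with empty
#'   hydrophobicity/membrane annotation; see [cg_topology()] to complete it.
#' @export
build_bead_chain <- function(structure) {
  ca <- structure$atoms[structure$atoms$atom == "CA", ]
  all_res <- sort(unique(structure$atoms$residue))
  missing_ca <- setdiff(all_res, ca$residue)
  if (length(missing_ca) > 0)
    stop("residue(s) without a C-alpha atom: ",
         paste(utils::head(missing_ca, 5), collapse = ", "))
  ca <- ca[order(ca$residue), ]
  new_bead_chain(
    tibble::tibble(residue = ca$residue, aa = structure$sequence,
                   x = ca$x, y = ca$y, z = ca$z))
}

# low-level constructor; validates the backbone sanity window
new_bead_chain <- function(df, contacts = NULL, chirality = NULL,
                           slab = NULL, warn_window = TRUE) {
  stopifnot(all(c("residue", "aa", "x", "y", "z") %in% names(df)))
  if (!"hydrophobic" %in% names(df)) df$hydrophobic <- NA
  if (!"membrane_contact" %in% names(df)) df$membrane_contact <- NA
  d <- sqrt(diff(df$x)^2 + diff(df$y)^2 + diff(df$z)^2)
  if (warn_window && any(d < 2.5 | d > 4.5))
    warning(sum(d < 2.5 | d > 4.5),
            " consecutive-bead distance(s) outside the [2.5, 4.5] A window")
  if (!is.null(contacts)) {
    stopifnot(all(contacts$j - contacts$i >= 2), all(contacts$sigma > 0))
  }
  out <- tibble::new_tibble(df, class = "bead_chain")
  attr(out, "contacts") <- contacts
  attr(out, "chirality") <- chirality
  attr(out, "slab") <- slab
  out
}

#' Native contact map from heavy-atom overlap
#'
#' Two residues i, j (with `j - i >= 2`) form a native contact when any pair
#' of their heavy atoms sits closer than `enlargement` times the sum of the
#' atoms' van der Waals radii. The contact length `sigma` is the native
#' C-alpha to C-alpha distance of the pair.
#'
#' @param structure An `atomistic_structure`.
#' @param vdw_table Optional named numeric vector of radii per element symbol
#'   (e.g. `c(C = 1.7)`); the default uses a Tsai-style per-atom-class table.
#' @param enlargement Enlargement factor on the radius sum.
#' @return Tibble (i, j, sigma) sorted by (i, j).
#' @export
native_contact_map <- function(structure, vdw_table = NULL,
                               enlargement = 1.244) {
  at <- structure$atoms
  if (is.null(vdw_table)) {
    key <- paste0(at$atom, ".", at$res_name)
    r <- .atom_radius(at$elem, key)
  } else {
    r <- unname(vdw_table[at$elem])
  }
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(at$elem[is.na(r)]), collapse = ", "))
  xyz <- cbind(at$x, at$y, at$z)
  dmat <- as.matrix(stats::dist(xyz))
  thr <- enlargement * outer(r, r, "+")
  sep <- abs(outer(at$residue, at$residue, "-"))
  hit <- which(dmat < thr & sep >= 2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0)
    return(tibble::tibble(i = integer(), j = integer(), sigma = numeric()))
  pairs <- unique(tibble::tibble(
    i = pmin(at$residue[hit[, 1]], at$residue[hit[, 2]]),
    j = pmax(at$residue[hit[, 1]], at$residue[hit[, 2]])))
  ca <- at[at$atom == "CA", ]
  ca <- ca[order(ca$residue), ]
  sig <- sqrt((ca$x[pairs$i] - ca$x[pairs$j])^2 +
              (ca$y[pairs$i] - ca$y[pairs$j])^2 +
              (ca$z[pairs$i] - ca$z[pairs$j])^2)
  dplyr::arrange(tibble::tibble(i = pairs$i, j = pairs$j, sigma = sig),
                 .data$i, .data$j)
}

#' Native contact map from C-alpha distances
#'
#' Distance-cutoff contact definition for bead-only (C-alpha) structures,
#' where the heavy-atom overlap criterion is not applicable. Pairs separated
#' by fewer than `min_sep` positions along the chain are excluded: at the
#' default 3 this drops (i, i+2) pairs, whose separation is fixed by backbone
#' geometry rather than tertiary structure (in a stretched chain they remain
#' within 1.5 sigma and would never register as broken). For the same reason
#' pairs whose rupture distance `1.5 sigma` exceeds 95% of the fully
#' stretched chain separation `d0 (j - i)` are excluded: such wells could
#' never be classified as broken by the native-contact bookkeeping.
#'
#' @param chain A `bead_chain`.
#' @param cutoff Contact cutoff on the C-alpha distance, A.
#' @param min_sep Minimum sequence separation `j - i`.
#' @param d0 Virtual bond length used for the stretched-chain screen, A.
#' @return Tibble (i, j, sigma).
#' @export
contact_map_calpha <- function(chain, cutoff = 7.5, min_sep = 3, d0 = 3.8) {
  xyz <- cbind(chain$x, chain$y, chain$z)
  dmat <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(nrow(xyz)), seq_len(nrow(xyz)), "-"))
  hit <- which(dmat < cutoff & sep >= min_sep, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  tibble::tibble(i = hit[, 1], j = hit[, 2],
                 sigma = dmat[hit]) |>
    dplyr::filter(1.5 * .data$sigma < 0.95 * d0 * (.data$j - .data$i)) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Flag residues in native contact with the membrane
#'
#' A residue is in membrane contact when its native C-alpha z coordinate lies
#' within the slab extended by the boundary ramp width on both sides.
#'
#' @param chain A `bead_chain` (native coordinates, membrane frame).
#' @param slab A [membrane_slab()].
#' @return Logical vector per residue.
#' @export
assign_membrane_contact <- function(chain, slab = membrane_slab()) {
  chain$z >= slab$z_min - slab$ramp_width &
    chain$z <= slab$z_max + slab$ramp_width
}

#' Native chirality of internal beads
#'
#' For bead i the chirality is the triple product of the three consecutive
#' virtual-bond vectors around it, `C_i = ((v_{i-1} x v_i) . v_{i+1}) / d0^3`
#' with `v_i = r_{i+1} - r_i`, evaluated on native coordinates. Defined for
#' beads 2..N-2; mirror-imaging the structure flips every sign.
#'
#' @param chain A `bead_chain` (or a numeric N x 3 matrix of positions).
#' @param d0 Virtual bond length used for normalisation, A.
#' @return Numeric vector of length N with `NA` at the undefined ends.
#' @export
native_chirality <- function(chain, d0 = 3.8) {
  pos <- if (is.matrix(chain)) chain else cbind(chain$x, chain$y, chain$z)
  n <- nrow(pos)
  out <- rep(NA_real_, n)
  if (n < 4) return(out)
  v <- diff(pos)  # v[i, ] = r_{i+1} - r_i
  for (i in 2:(n - 2)) {
    a <- v[i - 1, ]; b <- v[i, ]; cc <- v[i + 1, ]
    out[i] <- sum(c(a[2] * b[3] - a[3] * b[2],
                    a[3] * b[1] - a[1] * b[3],
                    a[1] * b[2] - a[2] * b[1]) * cc) / d0^3
  }
  out
}

#' Assemble the full coarse-grained topology
#'
#' Convenience wrapper: builds the bead chain from an atomistic structure and
#' attaches the native contact map, native chiralities, hydrophobicity classes
#' and membrane-contact flags.
#'
#' @param structure An `atomistic_structure`.
#' @param slab A [membrane_slab()].
#' @param vdw_table,enlargement Passed to [native_contact_map()].
#' @return A fully annotated `bead_chain`.
#' @export
cg_topology <- function(structure, slab = membrane_slab(), vdw_table = NULL,
                        enlargement = 1.244) {
  chain <- build_bead_chain(structure)
  chain$hydrophobic <- classify_hydrophobicity(chain$aa)
  chain$membrane_contact <- assign_membrane_contact(chain, slab)
  contacts <- native_contact_map(structure, vdw_table, enlargement)
  new_bead_chain(chain, contacts = contacts,
                 chirality = native_chirality(chain), slab = slab)
}

#' Add an explicit cross-link (e.g. a disulfide bond) to a topology
#'
#' Appends a permanent native contact between two beads at their native
#' separation, for cases where a covalent cross-link should be represented
#' beyond what the contact map already contains.
#'
#' @param chain An annotated `bead_chain`.
#' @param i,j Residue indices (`j - i >= 2`).
#' @return The chain with the extra contact.
#' @export
add_cross_link <- function(chain, i, j) {
  stopifnot(j - i >= 2)
  contacts <- attr(chain, "contacts")
  if (any(contacts$i == i & contacts$j == j)) return(chain)
  sigma <- sqrt((chain$x[i] - chain$x[j])^2 + (chain$y[i] - chain$y[j])^2 +
                (chain$z[i] - chain$z[j])^2)
  contacts <- dplyr::arrange(
    dplyr::bind_rows(contacts, tibble::tibble(i = i, j = j, sigma = sigma)),
    .data$i, .data$j)
  attr(chain, "contacts") <- contacts
  chain
}

#' Topology as a plain table
#'
#' @param chain An annotated `bead_chain`.
#' @return Tibble (i, j, sigma_ij_A) of native contacts, suitable for writing
#'   as tab-separated text.
#' @export
topology_table <- function(chain) {
  ct <- attr(chain, "contacts")
  tibble::tibble(i = ct$i, j = ct$j, sigma_ij_A = ct$sigma)
}

#' Topology as a JSON document
#'
#' Serialises the bead chain (positions, sequence, hydrophobicity and
#' membrane-contact flags), the native contact map, the native chiralities
#' and the membrane slab into one self-contained JSON string.
#'
#' @param chain An annotated `bead_chain`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
topology_json <- function(chain, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("topology_json() needs the jsonlite package")
  slab <- attr(chain, "slab")
  doc <- list(
    n_residues = nrow(chain),
    sequence = paste(chain$aa, collapse = ""),
    beads = tibble::as_tibble(chain)[, c("residue", "x", "y", "z",
                                         "hydrophobic",
                                         "membrane_contact")],
    contacts = topology_table(chain),
    chirality_native = attr(chain, "chirality"),
    slab = if (is.null(slab)) NULL else unclass(slab))
  out <- jsonlite::toJSON(doc, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA, null = "null")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# internal: package a bead_chain for the C++ engine
as_cg_topology <- function(chain) {
  ct <- attr(chain, "contacts")
  slab <- attr(chain, "slab")
  if (is.null(slab)) slab <- membrane_slab()
  chir <- attr(chain, "chirality")
  if (is.null(chir)) chir <- native_chirality(chain)
  hp <- chain$hydrophobic
  mc <- chain$membrane_contact
  if (all(is.na(hp))) hp <- rep(FALSE, nrow(chain))
  if (all(is.na(mc))) mc <- rep(FALSE, nrow(chain))
  list(contact_i = as.integer(ct$i), contact_j = as.integer(ct$j),
       contact_sigma = as.numeric(ct$sigma),
       chirality_native = as.numeric(chir),
       hydrophobic = as.integer(hp), membrane_contact = as.integer(mc),
       z_min = slab$z_min, z_max = slab$z_max)
}

chain_positions <- function(chain, positions = NULL) {
  if (!is.null(positions)) return(as.matrix(positions))
  cbind(chain$x, chain$y, chain$z)
}
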