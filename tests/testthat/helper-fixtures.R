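# fixtures are built in code: PDB text, ideal helices, small bead chains

pdb_line <- function(serial, name, resname, resno, x, y, z, elem,
                     occ = 1, record = "ATOM") {
  sprintf("%-6s%5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, resno, x, y, z, occ, 0, elem)
}

# three residues (ALA-GLY-SER) with backbone + CB heavy atoms
toy_pdb <- function(with_hydrogens = FALSE) {
  res <- c("ALA", "GLY", "SER")
  lines <- character()
  s <- 0
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    s <- s + 1; lines <- c(lines, pdb_line(s, "N", res[i], i, x0 - 1.2, 0.5, 0, "N"))
    s <- s + 1; lines <- c(lines, pdb_line(s, "CA", res[i], i, x0, 0, 0, "C"))
    s <- s + 1; lines <- c(lines, pdb_line(s, "C", res[i], i, x0 + 1.0, -1.0, 0, "C"))
    s <- s + 1; lines <- c(lines, pdb_line(s, "O", res[i], i, x0 + 1.0, -2.2, 0, "O"))
    if (res[i] != "GLY") {
      s <- s + 1
      lines <- c(lines, pdb_line(s, "CB", res[i], i, x0, 1.5, 0.3, "C"))
    }
    if (with_hydrogens) {
      s <- s + 1
      lines <- c(lines, pdb_line(s, "HA", res[i], i, x0, 0.2, 1.0, "H"))
      s <- s + 1
      lines <- c(lines, pdb_line(s, "H", res[i], i, x0 - 1.2, 1.4, 0, "H"))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# four CA-only residues, far apart, plus CB probes on residues 1 and 4 at a
# controlled separation (toy for the overlap-criterion arithmetic)
probe_pair_pdb <- function(cb_sep) {
  lines <- character()
  s <- 0
  for (i in 1:4) {
    s <- s + 1
    lines <- c(lines, pdb_line(s, "CA", "ALA", i, (i - 1) * 6, 0, 0, "C"))
  }
  s <- s + 1; lines <- c(lines, pdb_line(s, "CB", "ALA", 1, 0, 8, 0, "C"))
  s <- s + 1; lines <- c(lines, pdb_line(s, "CB", "ALA", 4, cb_sep, 8, 0, "C"))
  paste(c(lines, "END"), collapse = "\n")
}

# ideal right-handed alpha-helix C-alpha trace
helix_coords <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  t <- seq_len(n) - 1
  cbind(radius * cos(t * turn), radius * sin(t * turn), rise * t)
}

# assemble a bead_chain from raw positions (validation off for toys)
chain_fixture <- function(pos, contacts = NULL, hydrophobic = FALSE,
                          membrane_contact = FALSE, slab = membrane_slab(),
                          aa = "A") {
  n <- nrow(pos)
  df <- tibble::tibble(residue = seq_len(n), aa = rep_len(aa, n),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       hydrophobic = rep_len(hydrophobic, n),
                       membrane_contact = rep_len(membrane_contact, n))
  ch <- photopull:::new_bead_chain(df, contacts = contacts, slab = slab,
                                   warn_window = FALSE)
  attr(ch, "chirality") <- native_chirality(ch)
  ch
}

# helix chain with contacts placed at the Lennard-Jones minimum (close to,
# but not exactly at, a potential minimum; fine for generic dynamics tests)
relaxed_helix_chain <- function(n = 50) {
  pos <- helix_coords(n)
  ct <- contact_map_calpha(tibble::tibble(x = pos[, 1], y = pos[, 2],
                                          z = pos[, 3]))
  ct$sigma <- ct$sigma * 2^(-1 / 6)
  chain_fixture(pos, contacts = ct)
}

# two-strand hairpin whose native configuration is an exact potential
# minimum: all bonds at d0, every interacting pair a native contact with
# sigma at the Lennard-Jones minimum, everything else beyond d_cut
hairpin_chain <- function(n = 50) {
  stopifnot(n %% 2 == 0)
  m <- n / 2 - 1                       # up-strand length (apex bead extra)
  up <- cbind(0, 0, 3.8 * (0:(m - 1)))
  apex <- c(2.6, 0, 3.8 * (m - 1) + sqrt(3.8^2 - 2.6^2))
  n_down <- n - m - 1
  down <- cbind(5.2, 0, 3.8 * ((m - 1):(m - n_down)))
  pos <- rbind(up, apex, down)
  idx_up <- seq_len(m)
  idx_down <- (m + 2):n
  pairs <- NULL
  for (i in idx_up) {
    for (j in idx_down) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < 5.61 && j - i >= 2) pairs <- rbind(pairs, c(i, j, d))
    }
  }
  d_apex <- sqrt(sum((pos[m, ] - pos[m + 2, ])^2))
  if (d_apex < 5.61) pairs <- rbind(pairs, c(m, m + 2, d_apex))
  ct <- tibble::tibble(i = as.integer(pairs[, 1]),
                       j = as.integer(pairs[, 2]),
                       sigma = pairs[, 3] * 2^(-1 / 6))
  ct <- ct[!duplicated(ct[, 1:2]), ]
  chain_fixture(pos, contacts = dplyr::arrange(ct, i, j))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# cached large fixtures shared across test files
bundle_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$bundle)) env$bundle <- synthetic_tm_bundle()
    env$bundle
  }
})
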