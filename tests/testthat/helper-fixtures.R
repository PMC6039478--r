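## Shared fixtures: waters built from explicit geometry, tiny proteins,
## idealized PHE coordinates, and PDB/SDF writers for reader tests.

kB <- 0.0019872041

`%||%` <- function(a, b) if (is.null(a)) b else a

## One water row with O at `o` and the H-O-H bisector along `bisector`
## (H1-H2 axis along `haxis`), ideal TIP3P internal geometry.
make_water <- function(frame, mol, o, bisector = c(0, 0, 1),
                       haxis = c(1, 0, 0)) {
  z <- bisector / sqrt(sum(bisector^2))
  xr <- haxis - sum(haxis * z) * z
  x <- xr / sqrt(sum(xr^2))
  r_oh <- 0.9572; half <- (104.52 / 2) * pi / 180
  h1 <- o + r_oh * (sin(half) * x + cos(half) * z)
  h2 <- o + r_oh * (-sin(half) * x + cos(half) * z)
  data.frame(frame = frame, mol = mol, ox = o[1], oy = o[2], oz = o[3],
             h1x = h1[1], h1y = h1[2], h1z = h1[3],
             h2x = h2[1], h2y = h2[2], h2z = h2[3])
}

## Minimal protein from explicit atom rows.
make_protein <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  waterpharm::protein_structure(atoms)
}

protein_atom <- function(elety, element, pos, charge = 0, sigma = 3.4,
                         epsilon = 0.1, resid = "UNK", resno = 1L) {
  data.frame(eleno = 0L, resno = resno, resid = resid, elety = elety,
             element = element, x = pos[1], y = pos[2], z = pos[3],
             charge = charge, sigma = sigma, epsilon = epsilon,
             stringsAsFactors = FALSE)
}

## Idealized PHE residue: backbone + ring hexagon (1.39 A, z = 2 plane).
phe_atoms <- function() {
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ring <- t(sapply(0:5, function(k)
    c(4 + 1.39 * cos(pi * k / 3), -2 + 1.39 * sin(pi * k / 3), 2)))
  rbind(
    data.frame(elety = c("N", "CA", "C", "O", "CB"),
               x = c(0, 1.46, 2.0, 1.3, 2.1),
               y = c(0, 0, 1.3, 2.3, -1.0),
               z = c(0, 0, 0, 0, 1.0)),
    data.frame(elety = ring_names, x = ring[, 1], y = ring[, 2], z = ring[, 3]))
}

write_pdb_atoms <- function(df, path, resid = "PHE", resno = 1L) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(df)), df$elety, resid, resno, df$x, df$y, df$z,
    substr(df$elety, 1, 1))
  writeLines(c(lines, "END"), path)
  path
}

## TIP3P-like water dimer in near-optimal hydrogen-bond geometry: donor at
## the origin pointing one O-H at the acceptor 2.8 A along +x; acceptor
## hydrogens point away (+x hemisphere).
dimer_waters <- function(frame = 1L) {
  rbind(
    make_water(frame, 1L, c(0, 0, 0), bisector = c(0.612, 0, -0.791),
               haxis = c(0.791, 0, 0.612)),
    make_water(frame, 2L, c(2.8, 0, 0), bisector = c(1, 0, 0),
               haxis = c(0, 1, 0)))
}

## Independent double-loop LJ + Coulomb oracle (kcal/mol).
energy_oracle <- function(xyz1, q1, s1, e1, xyz2, q2, s2, e2) {
  tot <- 0
  for (i in seq_len(nrow(xyz1))) for (j in seq_len(nrow(xyz2))) {
    r <- sqrt(sum((xyz1[i, ] - xyz2[j, ])^2))
    tot <- tot + 332.0636 * q1[i] * q2[j] / r
    eps <- sqrt(e1[i] * e2[j])
    if (eps > 0) {
      sr6 <- ((s1[i] + s2[j]) / 2 / r)^6
      tot <- tot + 4 * eps * (sr6^2 - sr6)
    }
  }
  tot
}

water_q <- c(-0.834, 0.417, 0.417)
water_s <- c(3.15061, 0, 0)
water_e <- c(0.1521, 0, 0)

water_xyz <- function(row) {
  rbind(c(row$ox, row$oy, row$oz), c(row$h1x, row$h1y, row$h1z),
        c(row$h2x, row$h2y, row$h2z))
}

## Hydration-site stub carrying descriptors only (for the decision tree).
site_stub <- function(E, acceptor, donor, hdist = NA_real_,
                      center = c(0, 0, 0), donated_dir = c(0, 0, 1),
                      accepted_dir = c(0, 0, 1)) {
  structure(list(id = "S1", center = center, occupancy = 100L,
                 members = NULL, E_enthalpy = E, E_sw = E, E_ww = 0,
                 S_trans = -0.001, S_orient = -0.001,
                 donor_ratio = donor, acceptor_ratio = acceptor,
                 mean_donor_H_dist = hdist, donated_dir = donated_dir,
                 accepted_dir = accepted_dir),
            class = "hydration_site")
}

## A small fully-typed pharmacophore model for screening tests.
demo_model <- function(types = c("A", "D", "H", "R"),
                       pos = rbind(c(0, 0, 0), c(5, 0, 0),
                                   c(0, 5, 0), c(5, 5, 2))) {
  dirs <- lapply(types, function(tt)
    if (tt %in% c("A", "D", "R")) c(0, 0, 1) else c(NA_real_, NA_real_, NA_real_))
  f <- data.frame(id = sprintf("F%d", seq_along(types)), type = types,
                  x = pos[, 1], y = pos[, 2], z = pos[, 3],
                  dx = sapply(dirs, `[`, 1), dy = sapply(dirs, `[`, 2),
                  dz = sapply(dirs, `[`, 3), tol = 1.0,
                  sites = sprintf("S%d", seq_along(types)),
                  stringsAsFactors = FALSE)
  waterpharm::pharmacophore_model(f, list(target = "demo"))
}

## A deterministic mixed scene used by several tests.
demo_scene_spec <- function(n_frames = 400L, seed = 42L) {
  waterpharm::scene_spec(list(
    waterpharm::planted_site(c(0, 0, 0), type = "D"),
    waterpharm::planted_site(c(8, 0, 0), type = "A"),
    waterpharm::planted_site(c(0, 8, 0), type = "H"),
    waterpharm::planted_site(c(8, 8, 0), type = "R"),
    waterpharm::planted_site(c(16, 4, 0), type = "N"),
    waterpharm::planted_site(c(16, -5, 0), type = "P")),
    n_frames = n_frames, seed = seed)
}
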