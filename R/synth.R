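## Deterministic synthetic fixtures: pocket scenes with planted Gaussian
## hydration sites (plus the protein partner atoms that realise each
## intended feature type), and DUD-shaped active/decoy ligand libraries
## built around a pharmacophore model.

#' Describe a planted hydration site
#'
#' @param mean site mean position (length-3, Angstrom).
#' @param sigma isotropic positional spread, Angstrom.
#' @param occupancy per-frame emission probability in (0, 1].
#' @param type intended feature type: `"A"`, `"D"`, `"P"`, `"H"`, `"R"`,
#'   `"N"` or `"none"` (a bare site with no engineered environment). The
#'   generator plants the protein partners that make the hydration-site
#'   descriptors realise this type: donor/acceptor groups at hydrogen-bond
#'   geometry for polar types, a nonpolar carbon shell for `H`, an
#'   aromatic ring below the site for `R`; `N` expands into two acceptor
#'   sub-sites 3 Angstrom apart that merge downstream.
#' @param orientation `"concentrated"` or `"uniform"`; default is
#'   concentrated for polar types (the hydrogen-bond geometry must hold)
#'   and uniform otherwise.
#' @param angular_sigma rotational jitter of concentrated orientations,
#'   degrees; positive-ionizable sites default to a tighter 6 degrees (and
#'   sigma 0.2), emulating the near-locked geometry of a strongly bound
#'   water.
#' @return list of class `planted_site`.
#' @export
planted_site <- function(mean, sigma = NULL, occupancy = 1.0, type = "none",
                         orientation = NULL, angular_sigma = NULL) {
  type <- match.arg(type, c("A", "D", "P", "H", "R", "N", "none"))
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must lie in (0, 1]")
  if (is.null(sigma)) sigma <- if (type == "P") 0.2 else 0.3
  if (is.null(angular_sigma)) angular_sigma <- if (type == "P") 6 else 10
  if (is.null(orientation))
    orientation <- if (type %in% c("A", "D", "P", "N")) "concentrated" else "uniform"
  orientation <- match.arg(orientation, c("concentrated", "uniform"))
  structure(list(mean = as.numeric(mean), sigma = sigma,
                 occupancy = occupancy, type = type,
                 orientation = orientation, angular_sigma = angular_sigma),
            class = "planted_site")
}

#' Describe a synthetic pocket scene
#'
#' @param sites list of [planted_site()]; pairwise means must be at least
#'   3 Angstrom apart (validated here).
#' @param n_frames trajectory length in frames.
#' @param bulk_density density of the uniform bulk water band,
#'   waters/Angstrom^3.
#' @param bulk_width thickness of the rectangular bulk band around the
#'   pocket, Angstrom (0 disables bulk water).
#' @param bulk_gap clearance between the planted-site bounding box and the
#'   bulk band, Angstrom; keeps bulk waters outside steric-clash range of
#'   the planted waters, as pre-equilibrated solvent would be.
#' @param seed random seed; the seed fully determines the output.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(sites, n_frames = 1000L, bulk_density = 0.0334,
                       bulk_width = 2.0, bulk_gap = 4.0, seed = 42L) {
  means <- do.call(rbind, lapply(sites, `[[`, "mean"))
  if (length(sites) > 1L) {
    d <- as.matrix(stats::dist(means))
    diag(d) <- Inf
    if (min(d) < 3)
      stop("planted sites closer than 3 A: ",
           sprintf("%.2f A between sites %d and %d", min(d),
                   which(d == min(d), arr.ind = TRUE)[1, 1],
                   which(d == min(d), arr.ind = TRUE)[1, 2]))
  }
  structure(list(sites = sites, n_frames = as.integer(n_frames),
                 bulk_density = bulk_density, bulk_width = bulk_width,
                 bulk_gap = bulk_gap, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param path YAML file with fields `n_frames`, `bulk_density`,
#'   `bulk_width`, `seed` and a `sites` list of planted-site fields.
#' @export
read_scene_spec <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- lapply(y$sites, function(s)
    planted_site(mean = as.numeric(s$mean), sigma = s$sigma %||% 0.3,
                 occupancy = s$occupancy %||% 1.0, type = s$type %||% "none",
                 orientation = s$orientation,
                 angular_sigma = s$angular_sigma %||% 10))
  scene_spec(sites, n_frames = y$n_frames %||% 1000L,
             bulk_density = y$bulk_density %||% 0.0334,
             bulk_width = y$bulk_width %||% 2.0,
             bulk_gap = y$bulk_gap %||% 4.0, seed = y$seed %||% 42L)
}

## expand an "N" plant into two acceptor sub-sites 3 A apart along y
.expand_sites <- function(sites) {
  out <- list()
  for (s in sites) {
    if (s$type == "N") {
      for (sgn in c(-1, 1)) {
        sub <- s
        sub$type <- "A"
        sub$mean <- s$mean + c(0, sgn * 1.5, 0)
        ## donor shells point away from the partner sub-site
        sub$donor_az <- (if (sgn < 0) c(-150, -90, -30) else c(30, 90, 150)) *
          pi / 180
        out[[length(out) + 1L]] <- sub
      }
    } else out[[length(out) + 1L]] <- s
  }
  out
}

## protein partner atoms realising one site's intended type; returns an
## atom data.frame (possibly empty) and the site's base orientation matrix
.site_environment <- function(site, resno) {
  mu <- site$mean
  atom <- function(elety, element, pos, charge, sigma, epsilon, resid = "SIT")
    data.frame(eleno = 0L, resno = resno, resid = resid, elety = elety,
               element = element, x = pos[1], y = pos[2], z = pos[3],
               charge = charge, sigma = sigma, epsilon = epsilon,
               stringsAsFactors = FALSE)
  half <- (104.52 / 2) * pi / 180
  u1 <- c(sin(half), 0, cos(half))    # O-H directions of the base orientation
  u2 <- c(-sin(half), 0, cos(half))
  base <- diag(3)
  atoms <- NULL
  if (site$type == "D") {
    ## acceptor oxygens straight down both O-H vectors
    atoms <- rbind(atom("OA1", "O", mu + 2.90 * u1, -0.834, 3.15061, 0.1521),
                   atom("OA2", "O", mu + 2.90 * u2, -0.834, 3.15061, 0.1521))
  } else if (site$type == "P") {
    ## tighter anionic acceptors: donated H...X below the 1.5 A split
    atoms <- rbind(atom("OX1", "O", mu + 2.30 * u1, -1.0, 2.70, 0.17),
                   atom("OX2", "O", mu + 2.30 * u2, -1.0, 2.70, 0.17))
  } else if (site$type == "A") {
    ## three amine-like N-H donor groups below the site, H pointing at the
    ## water oxygen; acceptance is insensitive to the water's own
    ## orientation, so the site accepts ~3 bonds/frame. The positive donor
    ## hydrogen next to the water oxygen makes the site strongly enthalpic.
    azs <- site$donor_az %||% (c(0, 120, 240) * pi / 180)
    for (k in seq_along(azs)) {
      v <- c(0.766 * cos(azs[k]), 0.766 * sin(azs[k]), -0.643)
      heavy <- mu + 2.85 * v
      atoms <- rbind(atoms,
                     atom(paste0("ND", k), "N", heavy, 0.0, 3.25, 0.17),
                     atom(paste0("HD", k), "H", heavy - 0.96 * v, 0.45, 0, 0))
    }
  } else if (site$type == "H") {
    ## nonpolar carbon shell: 8 contacts within 4 A
    for (k in 0:7) {
      ang <- 2 * pi * k / 8
      pos <- mu + c(3.45 * cos(ang), 3.45 * sin(ang), -1.1)
      atoms <- rbind(atoms, atom(paste0("CS", k), "C", pos, 0, 3.3997, 0.1094))
    }
  } else if (site$type == "R") {
    ## idealized PHE ring 3.5 A below, normal pointing at the site
    names6 <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    ctr <- mu - c(0, 0, 3.5)
    for (k in 0:5) {
      ang <- 2 * pi * k / 6
      pos <- ctr + c(1.39 * cos(ang), 1.39 * sin(ang), 0)
      atoms <- rbind(atoms, atom(names6[k + 1], "C", pos, -0.115, 3.3997,
                                 0.086, resid = "PHE"))
    }
  }
  list(atoms = atoms, base = base)
}

## sample rotation matrices for one site across n frames
.site_orientations <- function(site, n) {
  if (site$orientation == "uniform") {
    Q <- random_quats(n)
    lapply(seq_len(n), function(i) quat_to_matrix(Q[i, ]))
  } else {
    sd_rad <- site$angular_sigma * pi / 180
    lapply(seq_len(n), function(i) {
      ax <- stats::rnorm(3)
      rotvec_matrix(unitv(ax) * stats::rnorm(1, 0, sd_rad))
    })
  }
}

#' Generate a synthetic pocket trajectory
#'
#' Per frame, each planted site emits (with its occupancy probability) a
#' water whose oxygen is Gaussian about the site mean and whose hydrogens
#' follow the site's orientation mode; uniform bulk-band waters surround
#' the pocket. The protein holds the partner atoms implied by each site's
#' intended type. Output is fully reproducible from the scene seed.
#'
#' @param spec [scene_spec()].
#' @return list: `frames` (`water_frames`), `protein`
#'   (`protein_structure`, or `NULL` when the scene has no partner atoms),
#'   `reference` (matrix of planted means, the pocket reference), `truth`
#'   (data.frame of planted means and intended types, `N` plants expanded).
#' @export
generate_trajectory <- function(spec) {
  .with_seed(spec$seed, {
    sites <- .expand_sites(spec$sites)
    atoms <- NULL
    for (k in seq_along(sites)) {
      env <- .site_environment(sites[[k]], resno = k)
      atoms <- rbind(atoms, env$atoms)
    }
    protein <- NULL
    if (!is.null(atoms) && nrow(atoms)) {
      atoms$eleno <- seq_len(nrow(atoms))
      protein <- protein_structure(atoms)
    }
    n <- spec$n_frames
    rows <- vector("list", length(sites) + 1L)
    for (k in seq_along(sites)) {
      s <- sites[[k]]
      present <- which(stats::runif(n) <= s$occupancy)
      np <- length(present)
      if (!np) next
      O <- matrix(rep(s$mean, each = np), np, 3) +
        matrix(stats::rnorm(3 * np, 0, s$sigma), np, 3)
      rots <- .site_orientations(s, np)
      h1 <- t(vapply(seq_len(np), function(i)
        O[i, ] + as.vector(rots[[i]] %*% .tip3p_hbody[1, ]), numeric(3)))
      h2 <- t(vapply(seq_len(np), function(i)
        O[i, ] + as.vector(rots[[i]] %*% .tip3p_hbody[2, ]), numeric(3)))
      rows[[k]] <- data.frame(frame = present, mol = k,
                              ox = O[, 1], oy = O[, 2], oz = O[, 3],
                              h1x = h1[, 1], h1y = h1[, 2], h1z = h1[, 3],
                              h2x = h2[, 1], h2y = h2[, 2], h2z = h2[, 3])
    }
    ## bulk band: rectangular shell around the pocket bounding box
    if (spec$bulk_width > 0 && spec$bulk_density > 0) {
      means <- do.call(rbind, lapply(sites, `[[`, "mean"))
      lo <- apply(means, 2, min) - spec$bulk_gap
      hi <- apply(means, 2, max) + spec$bulk_gap
      olo <- lo - spec$bulk_width; ohi <- hi + spec$bulk_width
      v_out <- prod(ohi - olo); v_in <- prod(hi - lo)
      lambda <- spec$bulk_density * (v_out - v_in)
      counts <- stats::rpois(n, lambda)
      total <- sum(counts)
      if (total > 0) {
        pts <- matrix(0, 0, 3)
        while (nrow(pts) < total) {
          m <- 2 * (total - nrow(pts)) + 16
          cand <- cbind(stats::runif(m, olo[1], ohi[1]),
                        stats::runif(m, olo[2], ohi[2]),
                        stats::runif(m, olo[3], ohi[3]))
          inner <- cand[, 1] > lo[1] & cand[, 1] < hi[1] &
            cand[, 2] > lo[2] & cand[, 2] < hi[2] &
            cand[, 3] > lo[3] & cand[, 3] < hi[3]
          pts <- rbind(pts, cand[!inner, , drop = FALSE])
        }
        pts <- pts[seq_len(total), , drop = FALSE]
        Q <- random_quats(total)
        h1 <- t(vapply(seq_len(total), function(i)
          pts[i, ] + as.vector(quat_to_matrix(Q[i, ]) %*% .tip3p_hbody[1, ]),
          numeric(3)))
        h2 <- t(vapply(seq_len(total), function(i)
          pts[i, ] + as.vector(quat_to_matrix(Q[i, ]) %*% .tip3p_hbody[2, ]),
          numeric(3)))
        rows[[length(sites) + 1L]] <- data.frame(
          frame = rep(seq_len(n), counts),
          mol = 1000L + unlist(lapply(counts, seq_len)),
          ox = pts[, 1], oy = pts[, 2], oz = pts[, 3],
          h1x = h1[, 1], h1y = h1[, 2], h1z = h1[, 3],
          h2x = h2[, 1], h2y = h2[, 2], h2z = h2[, 3])
      }
    }
    waters <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(waters) || !nrow(waters))
      stop("scene produced no waters (occupancies too low?)")
    truth <- do.call(rbind, lapply(seq_along(sites), function(k) data.frame(
      site = k, type = sites[[k]]$type, x = sites[[k]]$mean[1],
      y = sites[[k]]$mean[2], z = sites[[k]]$mean[3],
      stringsAsFactors = FALSE)))
    list(frames = water_frames(waters, n_frames = n, validate = FALSE),
         protein = protein,
         reference = do.call(rbind, lapply(spec$sites, `[[`, "mean")),
         truth = truth)
  })
}

## rigid fragment emitting one perceived feature of the requested type at
## position p with optional direction d; returns atoms + bonds
.feature_fragment <- function(type, p, d = NULL, rot = diag(3)) {
  rd <- function(v) as.vector(rot %*% v)
  if (is.null(d)) d <- rd(c(0, 0, 1))
  atoms <- function(el, pos, chg = 0) data.frame(
    element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = chg,
    stringsAsFactors = FALSE)
  if (type == "A") {
    pos <- rbind(p, p - 1.23 * d)                     # O, then carbonyl C
    list(atoms = atoms(c("O", "C"), pos),
         bonds = data.frame(i = 1L, j = 2L, order = 2, aromatic = FALSE))
  } else if (type == "D") {
    pos <- rbind(p, p - 1.47 * d)                     # N-H2, then C
    list(atoms = atoms(c("N", "C"), pos),
         bonds = data.frame(i = 1L, j = 2L, order = 1, aromatic = FALSE))
  } else if (type == "H") {
    u <- rd(c(1, 0, 0))
    pos <- rbind(p + 0.76 * u, p - 0.76 * u)
    list(atoms = atoms(c("C", "C"), pos),
         bonds = data.frame(i = 1L, j = 2L, order = 1, aromatic = FALSE))
  } else if (type == "R") {
    ## benzene in the plane perpendicular to d
    a <- unitv(if (abs(d[1]) < 0.9) c(1, 0, 0) - d[1] * d else c(0, 1, 0) - d[2] * d)
    b <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
           d[1] * a[2] - d[2] * a[1])
    pos <- t(vapply(0:5, function(k)
      p + 1.39 * (cos(pi * k / 3) * a + sin(pi * k / 3) * b), numeric(3)))
    list(atoms = atoms(rep("C", 6), pos),
         bonds = data.frame(i = 1:6, j = c(2:6, 1L), order = 1.5,
                            aromatic = TRUE))
  } else if (type == "N") {
    ## carboxylate with group centroid at p
    o1 <- 1.25 * rd(c(0.891, 0, 0.454)); o2 <- 1.25 * rd(c(-0.891, 0, 0.454))
    ctr_off <- (o1 + o2) / 3
    cpos <- p - ctr_off
    pos <- rbind(cpos, cpos + o1, cpos + o2, cpos - 1.52 * rd(c(0, 0, 1)))
    list(atoms = atoms(c("C", "O", "O", "C"), pos,
                       chg = c(0, -1, 0, 0)),
         bonds = data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                            order = c(1, 2, 1), aromatic = FALSE))
  } else if (type == "P") {
    pos <- rbind(p, p - 1.47 * rd(c(1, 0, 0)))       # N+, then C
    list(atoms = atoms(c("N", "C"), pos, chg = c(1, 0)),
         bonds = data.frame(i = 1L, j = 2L, order = 1, aromatic = FALSE))
  } else stop("unknown feature type: ", type)
}

.assemble_conformer <- function(model, positions, dirs, rots) {
  atoms <- NULL; bonds <- NULL; off <- 0L
  for (i in seq_len(nrow(model$features))) {
    fr <- .feature_fragment(model$features$type[i], positions[i, ],
                            dirs[[i]], rots[[i]])
    fr$bonds$i <- fr$bonds$i + off
    fr$bonds$j <- fr$bonds$j + off
    atoms <- rbind(atoms, fr$atoms)
    bonds <- rbind(bonds, fr$bonds)
    off <- off + nrow(fr$atoms)
  }
  list(atoms = atoms, bonds = bonds)
}

#' Generate a DUD-shaped active/decoy library for a model
#'
#' Actives are rigid multi-fragment molecules whose perceived feature
#' points reproduce the model feature positions up to a small jitter;
#' decoys carry the same feature multiset with all pairwise distances
#' scaled by a factor of 2.1--2.5, which perturbs every inter-feature
#' distance by more than twice the screening tolerance whenever model
#' features are at least 3 Angstrom apart.
#'
#' @param model non-empty `pharmacophore_model`.
#' @param n_active,n_decoy library composition.
#' @param seed random seed.
#' @param jitter maximum positional jitter of active features, Angstrom.
#' @return list: `ligands` (list of `ligand_record`) and `labels` (named
#'   character vector).
#' @export
generate_library <- function(model, n_active, n_decoy, seed = 7L,
                             jitter = 0.3) {
  if (!nrow(model$features)) stop("cannot build a library for an empty model")
  mf <- model$features
  mpos <- as.matrix(mf[, c("x", "y", "z")])
  dirs <- lapply(seq_len(nrow(mf)), function(i) {
    d <- c(mf$dx[i], mf$dy[i], mf$dz[i])
    if (anyNA(d)) NULL else d
  })
  .with_seed(seed, {
    ligands <- list(); labels <- character(0)
    for (a in seq_len(n_active)) {
      u <- stats::runif(nrow(mf))^(1 / 3) * jitter
      dd <- matrix(stats::rnorm(3 * nrow(mf)), nrow(mf), 3)
      dd <- dd / sqrt(rowSums(dd^2)) * u
      rots <- lapply(seq_len(nrow(mf)), function(i)
        quat_to_matrix(random_quats(1)[1, ]))
      cf <- .assemble_conformer(model, mpos + dd, dirs, rots)
      id <- sprintf("ACT%04d", a)
      ligands[[length(ligands) + 1L]] <- ligand_record(id, "active", list(cf))
      labels[id] <- "active"
    }
    for (d in seq_len(n_decoy)) {
      s <- stats::runif(1, 2.1, 2.5)
      ctr <- colMeans(mpos)
      scaled <- sweep(mpos, 2, ctr) * s + matrix(ctr, nrow(mpos), 3, byrow = TRUE)
      rots <- lapply(seq_len(nrow(mf)), function(i)
        quat_to_matrix(random_quats(1)[1, ]))
      cf <- .assemble_conformer(model, scaled, dirs, rots)
      id <- sprintf("DEC%04d", d)
      ligands[[length(ligands) + 1L]] <- ligand_record(id, "decoy", list(cf))
      labels[id] <- "decoy"
    }
    list(ligands = ligands, labels = labels)
  })
}
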