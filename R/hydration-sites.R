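## Hydration site analysis (HSA): pocket water selection, greedy 1 A-sphere
## density clustering, and per-site thermodynamic / hydrogen-bond
## descriptors.

#' HSA configuration
#'
#' @param pocket_radius pocket cutoff around the reference ligand, Angstrom.
#' @param site_radius hydration-site sphere radius, Angstrom.
#' @param bulk_density bulk water number density, waters/Angstrom^3.
#' @param occupancy_multiplier density excess required to retain a site
#'   (2 = twice bulk).
#' @param nonbonded_cutoff interaction cutoff for site energies, Angstrom.
#' @param hbond_dist_max,hbond_angle_max geometric hydrogen-bond criterion:
#'   donor--acceptor heavy-atom distance (Angstrom) and the angle at the
#'   donor between the donor-H bond and the donor--acceptor axis (degrees).
#' @param bulk_donated,bulk_accepted bulk-water reference hydrogen-bond
#'   counts per frame, used to normalise donor/acceptor ratios.
#' @param trans_bin histogram bin edge for translational entropy, Angstrom.
#' @param water_params TIP3P-style water nonbonded parameters (named list
#'   with `O` and `H`, each `c(charge, sigma, epsilon)`).
#' @param ww_half_factor apply a 1/2 factor to water-water energy (off by
#'   default: the site water's full interaction with its neighbours is
#'   counted once, from the site water's perspective).
#' @param c2_fold fold water C2 symmetry into the orientational-entropy
#'   estimator (halves the reference volume).
#' @return list of class `hsa_config`.
#' @export
hsa_config <- function(pocket_radius = 5.0, site_radius = 1.0,
                       bulk_density = 0.0334, occupancy_multiplier = 2.0,
                       nonbonded_cutoff = 8.0, hbond_dist_max = 3.5,
                       hbond_angle_max = 30.0, bulk_donated = 1.8,
                       bulk_accepted = 1.8, trans_bin = 0.25,
                       water_params = .tip3p_params,
                       ww_half_factor = FALSE, c2_fold = TRUE) {
  cfg <- list(pocket_radius = pocket_radius, site_radius = site_radius,
              bulk_density = bulk_density,
              occupancy_multiplier = occupancy_multiplier,
              nonbonded_cutoff = nonbonded_cutoff,
              hbond_dist_max = hbond_dist_max,
              hbond_angle_max = hbond_angle_max,
              bulk_donated = bulk_donated, bulk_accepted = bulk_accepted,
              trans_bin = trans_bin, water_params = water_params,
              ww_half_factor = ww_half_factor, c2_fold = c2_fold)
  num <- vapply(cfg[1:10], is.numeric, TRUE)
  if (any(unlist(cfg[1:10][num]) <= 0)) stop("all hsa_config values must be positive")
  class(cfg) <- "hsa_config"
  cfg
}

#' Site occupancy retention threshold
#'
#' Closed form: `occupancy_multiplier * bulk_density * (4/3) pi r^3 *
#' n_frames` -- the expected oxygen count in a site sphere at the stated
#' density multiple. With defaults and 10,000 frames this is about 2,800.
#'
#' @param cfg [hsa_config()].
#' @param n_frames frame count of the trajectory.
#' @return numeric threshold (continuous; clustering retains sites whose
#'   integer occupancy reaches `max(2, ceiling(threshold))`).
#' @export
occupancy_threshold <- function(cfg = hsa_config(), n_frames) {
  cfg$occupancy_multiplier * cfg$bulk_density *
    (4 / 3) * pi * cfg$site_radius^3 * n_frames
}

#' Frame count of a production sampling schedule
#'
#' @param production_ns production length, nanoseconds.
#' @param sampling_ps sampling interval, picoseconds.
#' @return number of frames (e.g. 10 ns sampled every 1 ps = 10,000).
#' @export
md_frame_count <- function(production_ns = 10, sampling_ps = 1) {
  production_ns * 1000 / sampling_ps
}

#' Select binding-pocket waters
#'
#' Retains, per frame, waters whose oxygen lies within `pocket_radius`
#' (inclusive) of any reference heavy atom; the frame count is unchanged.
#'
#' @param frames `water_frames`.
#' @param reference n x 3 matrix of reference ligand heavy-atom coordinates.
#' @param cfg [hsa_config()].
#' @return filtered `water_frames`.
#' @export
select_pocket_waters <- function(frames, reference, cfg = hsa_config()) {
  reference <- rbind(reference)
  if (!nrow(reference)) stop("reference coordinates must be non-empty")
  w <- frames$waters
  keep <- rep(FALSE, nrow(w))
  r2 <- cfg$pocket_radius^2
  for (k in seq_len(nrow(reference))) {
    d2 <- (w$ox - reference[k, 1])^2 + (w$oy - reference[k, 2])^2 +
      (w$oz - reference[k, 3])^2
    keep <- keep | d2 <= r2
  }
  if (!any(keep)) warning("pocket dehydrated: no water within pocket_radius ",
                          "of the reference in any frame")
  water_frames(w[keep, , drop = FALSE], n_frames = frames$n_frames,
               validate = FALSE)
}

## Cell-list neighbour machinery over unique oxygen positions.
.cell_key <- function(cellmat) paste(cellmat[, 1], cellmat[, 2], cellmat[, 3])

.gather_neighbors <- function(cell_env, cell_coord, rings = 1L) {
  offs <- seq(-rings, rings)
  out <- integer(0)
  for (da in offs) for (db in offs) for (dc in offs) {
    key <- paste(cell_coord[1] + da, cell_coord[2] + db, cell_coord[3] + dc)
    pts <- cell_env[[key]]
    if (!is.null(pts)) out <- c(out, pts)
  }
  out
}

#' Cluster pocket waters into hydration sites
#'
#' Greedy maximum-density clustering: candidate centers are the observed
#' oxygen positions of not-yet-excluded waters; the candidate whose
#' `site_radius` sphere holds the most remaining oxygens is recorded as a
#' site and those oxygens are excluded; this repeats while the best count
#' reaches the occupancy threshold (see [occupancy_threshold()]). Ties are
#' broken by the lowest (frame, molecule id) of the candidate water, so the
#' result does not depend on input row order.
#'
#' @param frames `water_frames` (typically after [select_pocket_waters()]).
#' @param cfg [hsa_config()].
#' @return list of `hydration_site` objects (id, center, occupancy, member
#'   observations), in discovery order.
#' @export
cluster_sites <- function(frames, cfg = hsa_config()) {
  w <- frames$waters
  if (!nrow(w)) return(list())
  w <- w[order(w$frame, w$mol), , drop = FALSE]
  xyz <- cbind(w$ox, w$oy, w$oz)
  r <- cfg$site_radius; r2 <- r^2
  thr <- max(2, ceiling(occupancy_threshold(cfg, frames$n_frames)))

  ## collapse exact duplicate positions (weights); canonical order is first
  ## occurrence in (frame, mol) order
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  first <- !duplicated(key)
  umap <- match(key, key[first])
  U <- xyz[first, , drop = FALSE]
  n <- nrow(U)
  wt <- tabulate(umap, nbins = n)

  cellmat <- floor(U / r)
  cell_env <- new.env(parent = emptyenv())
  keys <- .cell_key(cellmat)
  for (grp in split(seq_len(n), keys)) assign(keys[grp[1]], grp, cell_env)

  count_points <- function(idx) {
    cnt <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      cand <- .gather_neighbors(cell_env, cellmat[i, ])
      cand <- cand[wt[cand] > 0]
      d2 <- (U[cand, 1] - U[i, 1])^2 + (U[cand, 2] - U[i, 2])^2 +
        (U[cand, 3] - U[i, 3])^2
      cnt[k] <- sum(wt[cand][d2 <= r2])
    }
    cnt
  }

  counts <- rep(-1, n)
  act <- which(wt > 0)
  counts[act] <- count_points(act)
  sites <- list()
  repeat {
    best <- max(counts)
    if (best < thr) break
    pick <- which(counts == best)[1]  # lowest canonical index wins ties
    center <- U[pick, ]
    near <- .gather_neighbors(cell_env, cellmat[pick, ])
    near <- near[wt[near] > 0]
    d2 <- (U[near, 1] - center[1])^2 + (U[near, 2] - center[2])^2 +
      (U[near, 3] - center[3])^2
    excl <- near[d2 <= r2]
    members_obs <- which(umap %in% excl)
    site <- structure(list(id = sprintf("S%d", length(sites) + 1L),
                           center = unname(center),
                           occupancy = sum(wt[excl]),
                           members = data.frame(frame = w$frame[members_obs],
                                                mol = w$mol[members_obs])),
                      class = "hydration_site")
    sites[[length(sites) + 1L]] <- site
    wt[excl] <- 0
    counts[excl] <- -1
    ## counts change only for active points within 2r of the new center
    aff <- .gather_neighbors(cell_env, cellmat[pick, ], rings = 2L)
    aff <- aff[wt[aff] > 0]
    if (length(aff)) {
      d2a <- (U[aff, 1] - center[1])^2 + (U[aff, 2] - center[2])^2 +
        (U[aff, 3] - center[3])^2
      aff <- aff[d2a <= (2 * r)^2]
      if (length(aff)) counts[aff] <- count_points(aff)
    }
  }
  sites
}

## Member water coordinates (n x 9) for a site, plus row indices.
.member_rows <- function(site, frames) {
  w <- frames$waters
  idx <- match(paste(site$members$frame, site$members$mol),
               paste(w$frame, w$mol))
  if (anyNA(idx)) stop("site members not found in frame set")
  idx
}

.water_mats <- function(w, idx) {
  list(O = cbind(w$ox[idx], w$oy[idx], w$oz[idx]),
       H1 = cbind(w$h1x[idx], w$h1y[idx], w$h1z[idx]),
       H2 = cbind(w$h2x[idx], w$h2y[idx], w$h2z[idx]))
}

#' Site interaction enthalpy
#'
#' Mean per-observation interaction energy of the site water with the
#' protein (`E_sw`) and with all other waters in the same frame (`E_ww`),
#' evaluated as Lennard-Jones 12-6 plus Coulomb (332.0636 kcal A/(mol e^2))
#' over atoms whose oxygen (or protein atom) lies within
#' `nonbonded_cutoff` of the site water oxygen. `E_ww` counts the full pair
#' energy once, from the site water's perspective; set `ww_half_factor` in
#' the config to halve it.
#'
#' @param site `hydration_site` with members.
#' @param frames `water_frames` providing the environment.
#' @param protein `protein_structure` or `NULL` for a protein-free system.
#' @param cfg [hsa_config()].
#' @return list with `E_enthalpy`, `E_sw`, `E_ww` (kcal/mol).
#' @export
site_energy <- function(site, frames, protein = NULL, cfg = hsa_config()) {
  w <- frames$waters
  if (anyNA(w[, c("h1x", "h2x")])) stop("member water missing hydrogens")
  idx <- .member_rows(site, frames)
  wp <- cfg$water_params
  wq <- c(wp$O["charge"], wp$H["charge"], wp$H["charge"])
  ws <- c(wp$O["sigma"], wp$H["sigma"], wp$H["sigma"])
  we <- c(wp$O["epsilon"], wp$H["epsilon"], wp$H["epsilon"])
  cut2 <- cfg$nonbonded_cutoff^2
  pa <- if (!is.null(protein)) protein$atoms else NULL
  pxyz <- if (!is.null(pa)) as.matrix(pa[, c("x", "y", "z")]) else NULL
  frame_rows <- split(seq_len(nrow(w)), w$frame)
  e_sw <- e_ww <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    o <- c(w$ox[i], w$oy[i], w$oz[i])
    watoms <- rbind(o, c(w$h1x[i], w$h1y[i], w$h1z[i]),
                    c(w$h2x[i], w$h2y[i], w$h2z[i]))
    if (!is.null(pa)) {
      d2 <- (pxyz[, 1] - o[1])^2 + (pxyz[, 2] - o[2])^2 + (pxyz[, 3] - o[3])^2
      sel <- d2 <= cut2
      if (any(sel))
        e_sw[k] <- pair_energy(watoms, wq, ws, we,
                               pxyz[sel, , drop = FALSE], pa$charge[sel],
                               pa$sigma[sel], pa$epsilon[sel])
    }
    others <- frame_rows[[as.character(w$frame[i])]]
    others <- others[others != i]
    if (length(others)) {
      d2 <- (w$ox[others] - o[1])^2 + (w$oy[others] - o[2])^2 +
        (w$oz[others] - o[3])^2
      others <- others[d2 <= cut2]
      if (length(others)) {
        om <- .water_mats(w, others)
        oxyz <- rbind(om$O, om$H1, om$H2)
        no <- length(others)
        e_ww[k] <- pair_energy(watoms, wq, ws, we, oxyz,
                               rep(wq, each = no), rep(ws, each = no),
                               rep(we, each = no))
      }
    }
  }
  if (cfg$ww_half_factor) e_ww <- e_ww / 2
  list(E_enthalpy = mean(e_sw + e_ww), E_sw = mean(e_sw), E_ww = mean(e_ww))
}

#' Translational entropy of a hydration site (histogram method)
#'
#' Member oxygen positions are binned on a cubic grid of edge `trans_bin`
#' covering the site sphere; with `g_k = n_k / (N_frames * bulk_density *
#' V_k)`, `S_trans = -k_B * bulk_density * sum(g_k log g_k * V_k)` (empty
#' bins contribute zero). The reference is bulk density, so a uniform
#' distribution at exactly bulk density scores zero and any concentration
#' scores negative.
#'
#' @inheritParams site_energy
#' @return `S_trans` in kcal/(mol K), relative to bulk.
#' @export
site_entropy_trans <- function(site, frames, cfg = hsa_config()) {
  idx <- .member_rows(site, frames)
  w <- frames$waters
  O <- cbind(w$ox[idx], w$oy[idx], w$oz[idx])
  r <- cfg$site_radius; h <- cfg$trans_bin
  nb <- ceiling(2 * r / h)
  lo <- site$center - r
  bin <- pmin(pmax(floor(sweep(O, 2, lo) / h), 0), nb - 1)
  kid <- bin[, 1] + nb * bin[, 2] + nb * nb * bin[, 3]
  n_k <- table(kid)
  vk <- h^3
  g <- as.numeric(n_k) / (frames$n_frames * cfg$bulk_density * vk)
  -.kB * cfg$bulk_density * sum(g * log(g) * vk)
}

## quaternion right-multiplication by the C2 rotation about the body z
## (bisector) axis: q (x) (0,0,0,1) = (-z, y, -x, w)
.quat_c2 <- function(Q) cbind(-Q[, 4], Q[, 3], -Q[, 2], Q[, 1])

## nearest-neighbour geodesic distance (radians) among unit quaternions,
## after double-cover folding and optional C2 folding; chunked for memory.
.quat_nn_theta <- function(Q, c2_fold = TRUE, chunk = 512L) {
  n <- nrow(Q)
  Qt <- t(Q)
  Q2t <- if (c2_fold) t(.quat_c2(Q)) else NULL
  theta <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dots <- abs(Q[s:e, , drop = FALSE] %*% Qt)
    if (c2_fold) dots <- pmax(dots, abs(Q[s:e, , drop = FALSE] %*% Q2t))
    for (k in seq_len(e - s + 1L)) dots[k, s + k - 1L] <- -1
    theta[s:e] <- acos(pmin(apply(dots, 1, max), 1))
  }
  theta
}

#' Orientational entropy of a hydration site (nearest-neighbour estimator)
#'
#' Each member water's orientation is a unit quaternion (body frame: O at
#' the origin, H-O-H bisector along +z, H1-H2 axis along x), identified
#' with its negative (double cover) and, by default, folded over the water
#' C2 symmetry. With `theta_i` the geodesic distance to the nearest other
#' member and `V(theta) = pi (2 theta - sin 2 theta)` the rotation-space
#' ball volume,
#' `S_orient = k_B * (gamma + mean(log(N V(theta_i) / V_ref)))`,
#' `V_ref = pi^2` (halved under C2 folding) and `gamma` the
#' Euler-Mascheroni constant. The estimator is asymptotically zero on the
#' uniform distribution and strongly negative for locked orientations.
#'
#' @inheritParams site_energy
#' @return `S_orient` in kcal/(mol K), relative to uniform; `NA` when the
#'   site has fewer than 2 members (undefined).
#' @export
site_entropy_orient <- function(site, frames, cfg = hsa_config()) {
  idx <- .member_rows(site, frames)
  if (length(idx) < 2L) return(NA_real_)
  w <- frames$waters
  O <- cbind(w$ox[idx], w$oy[idx], w$oz[idx])
  oh1 <- cbind(w$h1x[idx], w$h1y[idx], w$h1z[idx]) - O
  oh2 <- cbind(w$h2x[idx], w$h2y[idx], w$h2z[idx]) - O
  Q <- water_quats(oh1, oh2)
  theta <- .quat_nn_theta(Q, cfg$c2_fold)
  vref <- if (cfg$c2_fold) pi^2 / 2 else pi^2
  vol <- pi * (2 * theta - sin(2 * theta))
  n <- length(theta)
  .kB * (.euler_gamma + mean(log(n * vol / vref)))
}

#' Hydrogen-bond statistics of a hydration site
#'
#' A donated hydrogen bond is counted for each (site-water H, acceptor
#' heavy atom X) pair with O...X within `hbond_dist_max` and the angle at
#' the site oxygen between O-H and O...X within `hbond_angle_max`;
#' acceptors are other water oxygens and protein polar-acceptor atoms.
#' Accepted bonds apply the symmetric criterion at the partner donor
#' (other waters, or protein polar donor hydrogens paired with their heavy
#' atom). Ratios are mean events per occupied frame as a percentage of the
#' configured bulk references, so values above 100% are possible.
#'
#' @inheritParams site_energy
#' @return list: `donor_ratio`, `acceptor_ratio` (percent of bulk),
#'   `mean_donor_H_dist` (mean H...X distance over donated bonds, `NA` if
#'   none), `donated_dir` (mean donated O->H unit vector), `accepted_dir`
#'   (unit vector from the mean accepted partner toward the site center),
#'   `n_donated`, `n_accepted` (total event counts).
#' @export
site_hbonds <- function(site, frames, protein = NULL, cfg = hsa_config()) {
  idx <- .member_rows(site, frames)
  w <- frames$waters
  dmax <- cfg$hbond_dist_max; amax <- cfg$hbond_angle_max
  pa <- if (!is.null(protein)) protein$atoms else NULL
  acc_idx <- if (!is.null(pa)) which(pa$polarity == "polar-acceptor") else integer(0)
  acc_xyz <- if (length(acc_idx)) as.matrix(pa[acc_idx, c("x", "y", "z")]) else NULL
  don <- if (!is.null(protein)) protein$donors else data.frame(h = integer(0), heavy = integer(0))
  frame_rows <- split(seq_len(nrow(w)), w$frame)
  n_don <- 0L; n_acc <- 0L
  hdist_sum <- 0; ddir_sum <- c(0, 0, 0); partner_sum <- c(0, 0, 0)

  cosmax <- cos(amax * pi / 180)
  check_donated <- function(o, h, X) {
    ## X: m x 3 acceptor heavy atoms
    dox <- sweep(X, 2, o)
    rox <- sqrt(rowSums(dox^2))
    ok <- rox <= dmax & rox > 1e-6
    if (!any(ok)) return(NULL)
    oh <- unitv(h - o)
    cosang <- (dox[ok, , drop = FALSE] %*% oh) / rox[ok]
    hit <- which(cosang >= cosmax)
    if (!length(hit)) return(NULL)
    Xh <- X[ok, , drop = FALSE][hit, , drop = FALSE]
    list(hx = sqrt(rowSums(sweep(Xh, 2, h)^2)), n = length(hit))
  }

  for (i in idx) {
    o <- c(w$ox[i], w$oy[i], w$oz[i])
    hs <- rbind(c(w$h1x[i], w$h1y[i], w$h1z[i]),
                c(w$h2x[i], w$h2y[i], w$h2z[i]))
    others <- frame_rows[[as.character(w$frame[i])]]
    others <- others[others != i]
    oO <- if (length(others)) cbind(w$ox[others], w$oy[others], w$oz[others]) else NULL
    ## --- donated
    acceptors <- rbind(oO, acc_xyz)
    if (!is.null(acceptors) && nrow(acceptors)) {
      for (a in 1:2) {
        res <- check_donated(o, hs[a, ], acceptors)
        if (!is.null(res)) {
          n_don <- n_don + res$n
          hdist_sum <- hdist_sum + sum(res$hx)
          ddir_sum <- ddir_sum + res$n * unitv(hs[a, ] - o)
        }
      }
    }
    ## --- accepted from other waters
    if (length(others)) {
      d2 <- rowSums(sweep(oO, 2, o)^2)
      close <- which(d2 <= dmax^2 & d2 > 1e-12)
      for (j in close) {
        oj <- oO[j, ]
        hj <- rbind(c(w$h1x[others[j]], w$h1y[others[j]], w$h1z[others[j]]),
                    c(w$h2x[others[j]], w$h2y[others[j]], w$h2z[others[j]]))
        vo <- unitv(o - oj)
        for (a in 1:2) {
          if (sum(unitv(hj[a, ] - oj) * vo) >= cosmax) {
            n_acc <- n_acc + 1L
            partner_sum <- partner_sum + oj
          }
        }
      }
    }
    ## --- accepted from protein donors
    if (nrow(don)) {
      hv <- as.matrix(pa[don$h, c("x", "y", "z"), drop = FALSE])
      hw <- as.matrix(pa[don$heavy, c("x", "y", "z"), drop = FALSE])
      dvec <- sweep(hw, 2, o, "-") * -1  # heavy -> site O
      rd <- sqrt(rowSums(dvec^2))
      for (j in which(rd <= dmax & rd > 1e-6)) {
        hh <- unitv(hv[j, ] - hw[j, ])
        if (sum(hh * (dvec[j, ] / rd[j])) >= cosmax) {
          n_acc <- n_acc + 1L
          partner_sum <- partner_sum + hw[j, ]
        }
      }
    }
  }
  occ <- length(idx)
  donated_dir <- if (n_don > 0) unitv(ddir_sum) else c(NA_real_, NA_real_, NA_real_)
  accepted_dir <- if (n_acc > 0) {
    mp <- partner_sum / n_acc
    v <- site$center - mp
    if (vnorm(v) > 1e-9) unitv(v) else c(NA_real_, NA_real_, NA_real_)
  } else c(NA_real_, NA_real_, NA_real_)
  list(donor_ratio = 100 * (n_don / occ) / cfg$bulk_donated,
       acceptor_ratio = 100 * (n_acc / occ) / cfg$bulk_accepted,
       mean_donor_H_dist = if (n_don > 0) hdist_sum / n_don else NA_real_,
       donated_dir = donated_dir, accepted_dir = accepted_dir,
       n_donated = n_don, n_accepted = n_acc)
}

#' Run the full hydration-site analysis
#'
#' Selects pocket waters (when a reference is given), clusters them into
#' sites and attaches all descriptors. Energies and hydrogen bonds are
#' evaluated against the complete frame set, not just the pocket subset.
#'
#' @param frames `water_frames`.
#' @param protein `protein_structure` or `NULL`.
#' @param reference optional n x 3 reference coordinates for pocket
#'   selection.
#' @param cfg [hsa_config()].
#' @return list of `hydration_site` objects carrying descriptor fields
#'   (`E_enthalpy`, `E_sw`, `E_ww`, `S_trans`, `S_orient`, `donor_ratio`,
#'   `acceptor_ratio`, `mean_donor_H_dist`, direction vectors), class
#'   `hydration_site_list`.
#' @export
analyze_hydration_sites <- function(frames, protein = NULL, reference = NULL,
                                    cfg = hsa_config()) {
  pocket <- if (!is.null(reference))
    select_pocket_waters(frames, reference, cfg) else frames
  sites <- cluster_sites(pocket, cfg)
  for (k in seq_along(sites)) {
    s <- sites[[k]]
    en <- site_energy(s, frames, protein, cfg)
    hb <- site_hbonds(s, frames, protein, cfg)
    s$E_enthalpy <- en$E_enthalpy; s$E_sw <- en$E_sw; s$E_ww <- en$E_ww
    s$S_trans <- site_entropy_trans(s, frames, cfg)
    s$S_orient <- site_entropy_orient(s, frames, cfg)
    s$donor_ratio <- hb$donor_ratio
    s$acceptor_ratio <- hb$acceptor_ratio
    s$mean_donor_H_dist <- hb$mean_donor_H_dist
    s$donated_dir <- hb$donated_dir
    s$accepted_dir <- hb$accepted_dir
    sites[[k]] <- s
  }
  structure(sites, class = "hydration_site_list")
}

#' Tabulate hydration sites
#'
#' @param sites result of [analyze_hydration_sites()] (or [cluster_sites()],
#'   in which case descriptor columns are `NA`).
#' @return data.frame with one row per site.
#' @export
sites_table <- function(sites) {
  g <- function(s, f) if (is.null(s[[f]])) NA_real_ else s[[f]]
  gd <- function(s, f, i) if (is.null(s[[f]])) NA_real_ else s[[f]][i]
  do.call(rbind, lapply(sites, function(s) data.frame(
    site = s$id, cx = s$center[1], cy = s$center[2], cz = s$center[3],
    occupancy = s$occupancy, E_enthalpy = g(s, "E_enthalpy"),
    E_sw = g(s, "E_sw"), E_ww = g(s, "E_ww"), S_trans = g(s, "S_trans"),
    S_orient = g(s, "S_orient"), donor_ratio = g(s, "donor_ratio"),
    acceptor_ratio = g(s, "acceptor_ratio"),
    mean_donor_H_dist = g(s, "mean_donor_H_dist"),
    ddx = gd(s, "donated_dir", 1), ddy = gd(s, "donated_dir", 2),
    ddz = gd(s, "donated_dir", 3), adx = gd(s, "accepted_dir", 1),
    ady = gd(s, "accepted_dir", 2), adz = gd(s, "accepted_dir", 3),
    stringsAsFactors = FALSE)))
}

#' Write / read a hydration-site table (tab-delimited)
#'
#' @param sites `hydration_site_list` or the data.frame from [sites_table()].
#' @param path file path.
#' @export
write_site_table <- function(sites, path) {
  tab <- if (is.data.frame(sites)) sites else sites_table(sites)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  structure(lapply(seq_len(nrow(tab)), function(i) {
    structure(list(id = tab$site[i],
                   center = c(tab$cx[i], tab$cy[i], tab$cz[i]),
                   occupancy = tab$occupancy[i],
                   members = NULL,
                   E_enthalpy = tab$E_enthalpy[i], E_sw = tab$E_sw[i],
                   E_ww = tab$E_ww[i], S_trans = tab$S_trans[i],
                   S_orient = tab$S_orient[i],
                   donor_ratio = tab$donor_ratio[i],
                   acceptor_ratio = tab$acceptor_ratio[i],
                   mean_donor_H_dist = tab$mean_donor_H_dist[i],
                   donated_dir = c(tab$ddx[i], tab$ddy[i], tab$ddz[i]),
                   accepted_dir = c(tab$adx[i], tab$ady[i], tab$adz[i])),
              class = "hydration_site")
  }), class = "hydration_site_list")
}

#' @export
print.hydration_site <- function(x, ...) {
  cat(sprintf("hydration_site %s: center (%.2f, %.2f, %.2f), occupancy %d\n",
              x$id, x$center[1], x$center[2], x$center[3], x$occupancy))
  if (!is.null(x$E_enthalpy) && !is.na(x$E_enthalpy))
    cat(sprintf("  E %.2f kcal/mol (sw %.2f, ww %.2f); donor %.0f%%, acceptor %.0f%%\n",
                x$E_enthalpy, x$E_sw, x$E_ww, x$donor_ratio, x$acceptor_ratio))
  invisible(x)
}

#' @export
print.hydration_site_list <- function(x, ...) {
  cat("hydration_site_list:", length(x), "site(s)\n")
  for (s in x) print(s)
  invisible(x)
}
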