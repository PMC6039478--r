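## Brute-force greedy clustering oracle: O(n^2) distances, no cell lists.
cluster_oracle <- function(frames, cfg = hsa_config()) {
  w <- frames$waters
  w <- w[order(w$frame, w$mol), ]
  xyz <- cbind(w$ox, w$oy, w$oz)
  thr <- max(2, ceiling(occupancy_threshold(cfg, frames$n_frames)))
  active <- rep(TRUE, nrow(w))
  out <- list()
  repeat {
    best_cnt <- -1; best_i <- NA
    for (i in which(active)) {
      d2 <- (xyz[active, 1] - xyz[i, 1])^2 + (xyz[active, 2] - xyz[i, 2])^2 +
        (xyz[active, 3] - xyz[i, 3])^2
      cnt <- sum(d2 <= cfg$site_radius^2)
      if (cnt > best_cnt) { best_cnt <- cnt; best_i <- i }
    }
    if (best_cnt < thr) break
    ctr <- xyz[best_i, ]
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    mem <- active & d2 <= cfg$site_radius^2
    out[[length(out) + 1L]] <- list(center = ctr, occupancy = sum(mem))
    active[mem] <- FALSE
  }
  out
}

test_that("pocket selection keeps waters within 5 A of the reference", {
  w <- rbind(make_water(1L, 1L, c(4.9, 0, 0)), make_water(1L, 2L, c(5.1, 0, 0)),
             make_water(1L, 3L, c(0, 0, 0)), make_water(2L, 1L, c(9, 9, 9)))
  fr <- water_frames(w, n_frames = 2L)
  ref <- rbind(c(0, 0, 0))
  sel <- select_pocket_waters(fr, ref, hsa_config())
  expect_equal(sel$n_frames, 2L)                 # frame count unchanged
  expect_setequal(paste(sel$waters$frame, sel$waters$mol), c("1 1", "1 3"))
  ## reference equal to a water's own O position: distance zero retains it
  sel0 <- select_pocket_waters(fr, rbind(c(9, 9, 9)), hsa_config())
  expect_equal(nrow(sel0$waters), 1L)
  expect_warning(select_pocket_waters(fr, rbind(c(100, 100, 100))),
                 "pocket dehydrated")
})

test_that("a permanently occupied position becomes one site; a single
           observation never does", {
  n <- 200L
  w <- do.call(rbind, lapply(seq_len(n), function(f)
    make_water(f, 1L, c(0, 0, 0))))
  fr <- water_frames(w, n_frames = n)
  sites <- cluster_sites(fr, hsa_config())
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$center, c(0, 0, 0))
  expect_equal(sites[[1]]$occupancy, n)
  expect_gt(sites[[1]]$occupancy, occupancy_threshold(hsa_config(), n))
  one <- water_frames(make_water(1L, 1L, c(0, 0, 0)), n_frames = 1L)
  expect_length(cluster_sites(one, hsa_config()), 0L)
})

test_that("two planted Gaussian clouds are recovered and match the
           exhaustive-count oracle", {
  spec <- scene_spec(list(planted_site(c(0, 0, 0), sigma = 0.3, type = "none"),
                          planted_site(c(6, 0, 0), sigma = 0.3, type = "none")),
                     n_frames = 500L, bulk_width = 0, seed = 42L)
  scene <- generate_trajectory(spec)
  sites <- cluster_sites(scene$frames, hsa_config())
  expect_length(sites, 2L)
  centers <- do.call(rbind, lapply(sites, `[[`, "center"))
  d1 <- min(sqrt(rowSums(sweep(centers, 2, c(0, 0, 0))^2)))
  d2 <- min(sqrt(rowSums(sweep(centers, 2, c(6, 0, 0))^2)))
  expect_lt(d1, 0.25)
  expect_lt(d2, 0.25)
  oracle <- cluster_oracle(scene$frames, hsa_config())
  expect_length(oracle, 2L)
  for (k in 1:2) {
    expect_equal(sites[[k]]$center, oracle[[k]]$center)
    expect_equal(sites[[k]]$occupancy, oracle[[k]]$occupancy)
  }
})

test_that("clustering is invariant to water order within frames and sites
           never share observations", {
  spec <- scene_spec(list(planted_site(c(0, 0, 0), type = "none"),
                          planted_site(c(4, 0, 0), type = "none"),
                          planted_site(c(0, 4, 0), type = "none")),
                     n_frames = 300L, seed = 9L)
  scene <- generate_trajectory(spec)
  sites <- cluster_sites(scene$frames, hsa_config())
  w2 <- scene$frames$waters
  set.seed(1); w2 <- w2[sample(nrow(w2)), ]
  sites2 <- cluster_sites(water_frames(w2, scene$frames$n_frames,
                                       validate = FALSE), hsa_config())
  expect_equal(lapply(sites, `[[`, "center"), lapply(sites2, `[[`, "center"))
  ## exclusivity: no observation in two sites; centers farther than r apart
  keys <- unlist(lapply(sites, function(s) paste(s$members$frame, s$members$mol)))
  expect_false(any(duplicated(keys)))
  ctr <- do.call(rbind, lapply(sites, `[[`, "center"))
  if (nrow(ctr) > 1) {
    dd <- as.matrix(dist(ctr)); diag(dd) <- Inf
    expect_true(all(dd > hsa_config()$site_radius))
  }
})

test_that("planted sites are recovered across seeds (parameter recovery)", {
  for (seed in 1:10) {
    k <- 2L + (seed %% 4L)          # 2..5 planted sites
    grid <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0), c(2.5, 2.5, 4))
    spec <- scene_spec(lapply(seq_len(k), function(i)
      planted_site(grid[i, ], sigma = 0.3, occupancy = 0.9, type = "none")),
      n_frames = 300L, seed = seed)
    scene <- generate_trajectory(spec)
    sites <- cluster_sites(scene$frames, hsa_config())
    expect_length(sites, k)
    centers <- do.call(rbind, lapply(sites, `[[`, "center"))
    for (i in seq_len(k)) {
      dmin <- min(sqrt(rowSums(sweep(centers, 2, grid[i, ])^2)))
      expect_lt(dmin, 0.25)
    }
  }
})

test_that("the occupancy threshold follows the closed form", {
  cfg <- hsa_config()
  expect_equal(occupancy_threshold(cfg, 10000),
               2 * 0.0334 * (4 / 3) * pi * 1^3 * 10000)
  cfg2 <- hsa_config(site_radius = 2, occupancy_multiplier = 3)
  expect_equal(occupancy_threshold(cfg2, 100),
               3 * 0.0334 * (4 / 3) * pi * 8 * 100)
})

test_that("site energies match the double-loop oracle on a water dimer", {
  w <- dimer_waters()
  fr <- water_frames(w, n_frames = 1L)
  site <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 1L,
                         members = data.frame(frame = 1L, mol = 1L)),
                    class = "hydration_site")
  en <- site_energy(site, fr, protein = NULL, cfg = hsa_config())
  exp_ww <- energy_oracle(water_xyz(w[1, ]), water_q, water_s, water_e,
                          water_xyz(w[2, ]), water_q, water_s, water_e)
  expect_equal(en$E_ww, exp_ww, tolerance = 1e-8)
  expect_equal(en$E_sw, 0)
  expect_equal(en$E_enthalpy, exp_ww, tolerance = 1e-8)
  expect_lt(exp_ww, -4)   # a hydrogen-bonded dimer is strongly attractive
  ## half-factor toggle
  en2 <- site_energy(site, fr, NULL, hsa_config(ww_half_factor = TRUE))
  expect_equal(en2$E_ww, exp_ww / 2, tolerance = 1e-8)
})

test_that("an isolated site water has zero energy and doubled charges
           quadruple the Coulomb part", {
  w1 <- make_water(1L, 1L, c(0, 0, 0))
  fr1 <- water_frames(w1, n_frames = 1L)
  site <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 1L,
                         members = data.frame(frame = 1L, mol = 1L)),
                    class = "hydration_site")
  expect_equal(site_energy(site, fr1, NULL, hsa_config())$E_enthalpy, 0)
  w <- dimer_waters()
  fr <- water_frames(w, n_frames = 1L)
  base <- waterpharm:::.tip3p_params
  zero <- base; zero$O["charge"] <- 0; zero$H["charge"] <- 0
  dbl <- base; dbl$O["charge"] <- 2 * base$O["charge"]
  dbl$H["charge"] <- 2 * base$H["charge"]
  e1 <- site_energy(site, fr, NULL, hsa_config(water_params = base))$E_ww
  e0 <- site_energy(site, fr, NULL, hsa_config(water_params = zero))$E_ww
  e2 <- site_energy(site, fr, NULL, hsa_config(water_params = dbl))$E_ww
  expect_equal(e2 - e0, 4 * (e1 - e0), tolerance = 1e-9)
})

test_that("translational entropy is zero at bulk density, negative when
           concentrated, and matches a re-binning oracle", {
  ## one occupied bin holding exactly N_frames * rho * V waters -> g = 1
  cfg <- hsa_config(bulk_density = 0.5, trans_bin = 1.0)
  w <- do.call(rbind, lapply(1:5, function(f)
    make_water(f, 1L, c(0.2, 0.2, 0.2))))
  fr <- water_frames(w, n_frames = 10L)
  site <- structure(list(id = "S1", center = c(0.2, 0.2, 0.2), occupancy = 5L,
                         members = data.frame(frame = 1:5, mol = 1L)),
                    class = "hydration_site")
  expect_equal(site_entropy_trans(site, fr, cfg), 0)
  ## all members in one fine bin: strongly negative by construction
  expect_lt(site_entropy_trans(site, fr, hsa_config()), 0)
  ## Gaussian cloud vs independent histogram oracle
  spec <- scene_spec(list(planted_site(c(0, 0, 0), sigma = 0.3,
                                       occupancy = 0.5, type = "none")),
                     n_frames = 800L, bulk_width = 0, seed = 5L)
  scene <- generate_trajectory(spec)
  sites <- cluster_sites(scene$frames, hsa_config())
  s <- sites[[1]]
  got <- site_entropy_trans(s, scene$frames, hsa_config())
  ## oracle: explicit loop over member positions
  cfg0 <- hsa_config()
  w0 <- scene$frames$waters
  idx <- match(paste(s$members$frame, s$members$mol),
               paste(w0$frame, w0$mol))
  h <- cfg0$trans_bin; r <- cfg0$site_radius
  nb <- ceiling(2 * r / h)
  counts <- new.env()
  for (i in idx) {
    b <- pmin(pmax(floor((c(w0$ox[i], w0$oy[i], w0$oz[i]) -
                            (s$center - r)) / h), 0), nb - 1)
    key <- paste(b, collapse = ",")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  ssum <- 0
  for (key in ls(counts)) {
    g <- counts[[key]] / (scene$frames$n_frames * cfg0$bulk_density * h^3)
    ssum <- ssum + g * log(g) * h^3
  }
  expect_equal(got, -kB * cfg0$bulk_density * ssum, tolerance = 1e-10)
  expect_lt(got, 0)
})

test_that("orientational entropy vanishes on uniform orientations and
           diverges negative for locked ones", {
  n <- 10000L
  spec <- scene_spec(list(planted_site(c(0, 0, 0), sigma = 0.1,
                                       type = "none")),
                     n_frames = n, bulk_width = 0, seed = 17L)
  scene <- generate_trajectory(spec)   # "none" sites sample uniform orientations
  site <- cluster_sites(scene$frames, hsa_config())[[1]]
  s_or <- site_entropy_orient(site, scene$frames, hsa_config())
  expect_lt(abs(s_or) / kB, 0.05)
  ## near-identical orientations (tiny jitter): strongly negative
  spec2 <- scene_spec(list(planted_site(c(0, 0, 0), sigma = 0.05,
                                        type = "none",
                                        orientation = "concentrated",
                                        angular_sigma = 1e-4)),
                      n_frames = 400L, bulk_width = 0, seed = 3L)
  scene2 <- generate_trajectory(spec2)
  site2 <- cluster_sites(scene2$frames, hsa_config())[[1]]
  expect_lt(site_entropy_orient(site2, scene2$frames, hsa_config()), -5 * kB)
})

test_that("two orientations a quarter-turn apart match the closed form", {
  ## water 1: bisector +z; water 2: the same flipped by pi about x ->
  ## folded quaternion distance pi/2
  w <- rbind(make_water(1L, 1L, c(0, 0, 0), bisector = c(0, 0, 1)),
             make_water(2L, 1L, c(0, 0, 0), bisector = c(0, 0, -1),
                        haxis = c(1, 0, 0)))
  fr <- water_frames(w, n_frames = 2L)
  site <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 2L,
                         members = data.frame(frame = 1:2, mol = 1L)),
                    class = "hydration_site")
  got <- site_entropy_orient(site, fr, hsa_config())
  theta <- pi / 2
  v <- pi * (2 * theta - sin(2 * theta))
  expected <- kB * (0.5772156649015329 + mean(log(2 * v / (pi^2 / 2))))
  expect_equal(got, expected, tolerance = 1e-10)
  ## undefined below two members
  one <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 1L,
                        members = data.frame(frame = 1L, mol = 1L)),
                   class = "hydration_site")
  expect_true(is.na(site_entropy_orient(one, fr, hsa_config())))
})

test_that("hydrogen-bond ratios follow the bulk normalisation", {
  ## donating to exactly one protein acceptor every frame: 100 * 1 / 1.8
  n <- 25L
  w <- do.call(rbind, lapply(seq_len(n), function(f)
    make_water(f, 1L, c(0, 0, 0), bisector = c(0.612, 0, -0.791),
               haxis = c(0.791, 0, 0.612))))
  fr <- water_frames(w, n_frames = n)
  prot <- make_protein(protein_atom("OX", "O", c(2.8, 0, 0), charge = -0.8))
  site <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = n,
                         members = data.frame(frame = seq_len(n), mol = 1L)),
                    class = "hydration_site")
  hb <- site_hbonds(site, fr, prot, hsa_config())
  expect_equal(hb$donor_ratio, 100 * 1 / 1.8, tolerance = 1e-9)
  expect_equal(hb$acceptor_ratio, 0)
  ## H...X distance: the H sits on the O-O axis, 0.9572 from the donor O
  expect_equal(hb$mean_donor_H_dist, 2.8 - 0.9572, tolerance = 1e-3)
  expect_equal(hb$donated_dir, c(1, 0, 0), tolerance = 1e-3)
  ## no partners anywhere: both ratios zero, distance undefined
  lone <- water_frames(make_water(1L, 1L, c(0, 0, 0)), 1L)
  site1 <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 1L,
                          members = data.frame(frame = 1L, mol = 1L)),
                     class = "hydration_site")
  hb0 <- site_hbonds(site1, lone, NULL, hsa_config())
  expect_equal(hb0$donor_ratio, 0)
  expect_equal(hb0$acceptor_ratio, 0)
  expect_true(is.na(hb0$mean_donor_H_dist))
})

test_that("a linear water dimer donates one bond and accepts one", {
  w <- dimer_waters()
  fr <- water_frames(w, n_frames = 1L)
  donor_site <- structure(list(id = "S1", center = c(0, 0, 0), occupancy = 1L,
                               members = data.frame(frame = 1L, mol = 1L)),
                          class = "hydration_site")
  acceptor_site <- structure(list(id = "S2", center = c(2.8, 0, 0),
                                  occupancy = 1L,
                                  members = data.frame(frame = 1L, mol = 2L)),
                             class = "hydration_site")
  hb_d <- site_hbonds(donor_site, fr, NULL, hsa_config())
  hb_a <- site_hbonds(acceptor_site, fr, NULL, hsa_config())
  expect_equal(hb_d$n_donated, 1L)
  expect_equal(hb_d$n_accepted, 0L)
  expect_equal(hb_a$n_accepted, 1L)
  ## direct geometric oracle for the donated event
  o <- c(w$ox[1], w$oy[1], w$oz[1]); h1 <- c(w$h1x[1], w$h1y[1], w$h1z[1])
  x <- c(w$ox[2], w$oy[2], w$oz[2])
  ang <- acos(sum((h1 - o) * (x - o)) /
                (sqrt(sum((h1 - o)^2)) * sqrt(sum((x - o)^2)))) * 180 / pi
  expect_lt(ang, 30)
  expect_lt(sqrt(sum((x - o)^2)), 3.5)
})
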