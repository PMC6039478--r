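benzene_conformer <- function(center = c(0, 0, 0)) {
  pos <- t(sapply(0:5, function(k)
    center + 1.39 * c(cos(pi * k / 3), sin(pi * k / 3), 0)))
  list(atoms = data.frame(element = "C", x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], charge = 0),
       bonds = data.frame(i = 1:6, j = c(2:6, 1L), order = 1.5,
                          aromatic = TRUE))
}

acetate_conformer <- function() {
  list(atoms = data.frame(element = c("C", "O", "O", "C"),
                          x = c(0, 1.11, -1.11, 0),
                          y = c(0, 0.57, 0.57, -1.52), z = 0.1,
                          charge = c(0, -1, 0, 0)),
       bonds = data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                          order = c(1, 2, 1), aromatic = FALSE))
}

test_that("template molecules perceive their canonical features", {
  ace <- perceive_features(acetate_conformer())
  expect_equal(ace$type, "N")
  ctr <- colMeans(rbind(c(0, 0, 0.1), c(1.11, 0.57, 0.1), c(-1.11, 0.57, 0.1)))
  expect_equal(c(ace$x, ace$y, ace$z), ctr, tolerance = 1e-9)
  bz <- perceive_features(benzene_conformer())
  expect_equal(bz$type, "R")
  expect_equal(abs(bz$dz), 1, tolerance = 1e-9)
})

test_that("a biotin-like fragment set matches hand-enumerated features", {
  ## ureido N-C(=O)-N with flanking carbons, a thioether chain and a
  ## carboxylate tail: hand enumeration gives
  ##   N1: D+A (one implicit H, lone pair)   N4: D+A
  ##   O3: A; carboxylate -> N; chain C5-C6: H; no rings
  atoms <- data.frame(
    element = c("N", "C", "O", "N", "C", "C", "S", "C", "O", "O"),
    x = c(0, 1.3, 1.3, 2.6, -1.0, -1.8, 3.6, 6.0, 7.1, 5.9),
    y = c(0, 0.8, 2.0, 0, -1.2, -2.4, -1.0, 0, 0.6, -1.3),
    z = 0.5, charge = c(0, 0, 0, 0, 0, 0, 0, 0, -1, 0))
  bonds <- data.frame(i = c(1L, 2L, 2L, 1L, 5L, 4L, 8L, 8L),
                      j = c(2L, 3L, 4L, 5L, 6L, 7L, 9L, 10L),
                      order = c(1, 2, 1, 1, 1, 1, 1, 2), aromatic = FALSE)
  f <- perceive_features(list(atoms = atoms, bonds = bonds))
  expect_equal(sort(table(f$type)[c("A", "D", "H", "N")]),
               sort(c(A = 3L, D = 2L, H = 1L, N = 1L)), ignore_attr = TRUE)
  expect_equal(sum(f$type == "R"), 0L)
})

test_that("an exact-geometry ligand matches with zero RMSD", {
  model <- demo_model()
  lf <- data.frame(type = model$features$type, x = model$features$x,
                   y = model$features$y, z = model$features$z,
                   dx = model$features$dx, dy = model$features$dy,
                   dz = model$features$dz)
  res <- match_conformer(model, lf, screen_config())
  expect_true(res$accepted)
  expect_equal(res$alignment_score, 0, tolerance = 1e-9)
  expect_equal(res$vector_score, 1, tolerance = 1e-9)
  expect_gte(res$volume_score, 0)
})

test_that("an inter-feature distance off by 1.6 A prunes the correspondence", {
  model <- demo_model(types = c("A", "D"), pos = rbind(c(0, 0, 0), c(4, 0, 0)))
  lf <- data.frame(type = c("A", "D"), x = c(0, 5.6), y = 0, z = 0,
                   dx = c(0, 0), dy = c(0, 0), dz = c(1, 1))
  expect_null(match_conformer(model, lf, screen_config()))
  ## 1.4 A off survives pruning
  lf2 <- lf; lf2$x[2] <- 5.4
  expect_false(is.null(match_conformer(model, lf2, screen_config())))
})

test_that("a saddle distortion with post-fit RMSD above 1.2 A is rejected", {
  sq <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0))
  model <- demo_model(types = rep("H", 4), pos = sq)
  h <- 1.3
  lig <- sq + cbind(0, 0, c(h, -h, h, -h))
  lf <- data.frame(type = "H", x = lig[, 1], y = lig[, 2], z = lig[, 3],
                   dx = NA_real_, dy = NA_real_, dz = NA_real_)
  res <- match_conformer(model, lf, screen_config())
  expect_false(is.null(res))
  expect_gt(res$alignment_score, 1.2)
  expect_false(res$accepted)
})

test_that("Kabsch superposition beats random rigid placements", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 3), n, 3)
    fit <- waterpharm:::kabsch_fit(P, Q)
    for (k in 1:100) {
      R <- waterpharm:::rotvec_matrix(rnorm(3))
      tv <- rnorm(3)
      rmsd_k <- sqrt(mean(rowSums((waterpharm:::apply_rigid(P, R, tv) - Q)^2)))
      expect_gte(rmsd_k, fit$rmsd - 1e-9)
    }
  }
})

test_that("scores are invariant under rigid motion of the conformer", {
  model <- demo_model()
  lib <- generate_library(model, 1, 0, seed = 12)
  cf <- lib$ligands[[1]]$conformers[[1]]
  res1 <- match_conformer(model, perceive_features(cf), screen_config(),
                          lig_atoms = cf$atoms)
  set.seed(8)
  R <- waterpharm:::rotvec_matrix(rnorm(3)); tv <- runif(3, -10, 10)
  cf2 <- cf
  xyz <- waterpharm:::apply_rigid(as.matrix(cf$atoms[, c("x", "y", "z")]), R, tv)
  cf2$atoms$x <- xyz[, 1]; cf2$atoms$y <- xyz[, 2]; cf2$atoms$z <- xyz[, 3]
  res2 <- match_conformer(model, perceive_features(cf2), screen_config(),
                          lig_atoms = cf2$atoms)
  expect_equal(res2$alignment_score, res1$alignment_score, tolerance = 1e-9)
  expect_equal(res2$vector_score, res1$vector_score, tolerance = 1e-9)
  expect_equal(res2$volume_score, res1$volume_score, tolerance = 1e-9)
  expect_equal(res2$fitness, res1$fitness, tolerance = 1e-9)
})

test_that("the backtracking search agrees with exhaustive enumeration", {
  ## oracle: all injective type-compatible maps, filtered by distance
  ## consistency, scored the same way; compare the chosen correspondence
  brute_best <- function(model, lf, cfg) {
    mf <- model$features
    nm <- nrow(mf)
    mpos <- as.matrix(mf[, c("x", "y", "z")])
    lpos <- as.matrix(lf[, c("x", "y", "z")])
    dm <- as.matrix(dist(mpos)); dl <- as.matrix(dist(lpos))
    idx <- seq_len(nrow(lf))
    best <- NULL
    rec <- function(k, cur) {
      if (k > nm) {
        fit <- waterpharm:::kabsch_fit(lpos[cur, , drop = FALSE], mpos)
        if (is.null(best) || fit$rmsd < best$rmsd)
          best <<- list(map = cur, rmsd = fit$rmsd)
        return()
      }
      comp <- switch(mf$type[k], N = c("N", "A"), P = c("P", "D"), mf$type[k])
      for (j in idx[lf$type %in% comp]) {
        if (j %in% cur) next
        ok <- all(vapply(seq_len(k - 1), function(p)
          abs(dm[p, k] - dl[cur[p], j]) <= cfg$dist_tolerance, TRUE))
        if (ok) rec(k + 1, c(cur, j))
      }
    }
    rec(1L, integer(0))
    best
  }
  set.seed(77)
  for (rep in 1:5) {
    nm <- sample(2:4, 1)
    mpos <- matrix(runif(3 * nm, 0, 8), nm, 3)
    types <- sample(c("A", "D", "H", "N"), nm, replace = TRUE)
    model <- demo_model(types = types, pos = mpos)
    nl <- sample(4:6, 1)
    lpos <- rbind(mpos + matrix(rnorm(3 * nm, sd = 0.2), nm, 3),
                  matrix(runif(3 * (nl - nm), 0, 8), nl - nm, 3))
    lf <- data.frame(type = c(types, sample(c("A", "H"), nl - nm, TRUE)),
                     x = lpos[, 1], y = lpos[, 2], z = lpos[, 3],
                     dx = NA_real_, dy = NA_real_, dz = NA_real_)
    lf$dx[lf$type %in% c("A", "D")] <- 0
    lf$dy[lf$type %in% c("A", "D")] <- 0
    lf$dz[lf$type %in% c("A", "D")] <- 1
    cfg <- screen_config(w_vec = 0, w_vol = 0)  # fitness = alignment only
    res <- match_conformer(model, lf, cfg)
    oracle <- brute_best(model, lf, cfg)
    if (is.null(oracle)) {
      expect_null(res)
    } else {
      expect_equal(unname(res$correspondence), oracle$map)
      expect_equal(res$alignment_score, oracle$rmsd, tolerance = 1e-9)
    }
  }
})

test_that("default vector and volume cutoffs never reject anything", {
  set.seed(91)
  for (rep in 1:10) {
    nm <- sample(2:4, 1)
    model <- demo_model(types = sample(c("A", "D", "H", "R"), nm, TRUE),
                        pos = matrix(runif(3 * nm, 0, 8), nm, 3))
    lf <- model$features[, c("type", "x", "y", "z", "dx", "dy", "dz")]
    ## randomize directions: vector score may drop but never below -1
    k <- sum(!is.na(lf$dx))
    if (k) {
      d <- matrix(rnorm(3 * k), k, 3); d <- d / sqrt(rowSums(d^2))
      lf[!is.na(lf$dx), c("dx", "dy", "dz")] <- d
    }
    res <- match_conformer(model, lf, screen_config())
    expect_gte(res$vector_score, -1)
    expect_gte(res$volume_score, 0)
    expect_true(res$accepted)   # alignment 0: only active gate passes
  }
})

test_that("actives outrank scrambled decoys and empty libraries are legal", {
  model <- demo_model()
  lib <- generate_library(model, 3, 3, seed = 4)
  hits <- screen_library(model, lib$ligands)
  expect_true(all(startsWith(hits$ligand, "ACT")))
  expect_equal(attr(hits, "status"), "ok")
  decoys_only <- generate_library(model, 0, 4, seed = 5)
  hits0 <- screen_library(model, decoys_only$ligands)
  expect_equal(nrow(hits0), 0L)
})
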