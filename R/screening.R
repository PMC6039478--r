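## Pharmacophore screening: ligand feature perception, distance-consistent
## correspondence search, Kabsch superposition and the alignment / vector /
## volume scores with their reject cutoffs.

#' Screening configuration
#'
#' @param dist_tolerance inter-feature distance matching tolerance,
#'   Angstrom.
#' @param align_reject reject matches whose post-fit RMSD exceeds this,
#'   Angstrom.
#' @param vector_reject reject matches whose mean direction cosine falls
#'   below this; the default (-1) never rejects.
#' @param volume_reject reject matches whose volume overlap fraction falls
#'   below this; the default (0) never rejects.
#' @param min_match `"all"` (every model feature must match) or an integer
#'   for opt-in partial matching.
#' @param w_align,w_vec,w_vol fitness weights.
#' @param mc_points,mc_seed Monte-Carlo sample size and seed for the
#'   volume score.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(dist_tolerance = 1.5, align_reject = 1.2,
                          vector_reject = -1.0, volume_reject = 0.0,
                          min_match = "all", w_align = 1, w_vec = 1,
                          w_vol = 1, mc_points = 10000L, mc_seed = 7L) {
  if (dist_tolerance <= 0) stop("dist_tolerance must be positive")
  structure(list(dist_tolerance = dist_tolerance, align_reject = align_reject,
                 vector_reject = vector_reject, volume_reject = volume_reject,
                 min_match = min_match, w_align = w_align, w_vec = w_vec,
                 w_vol = w_vol, mc_points = as.integer(mc_points),
                 mc_seed = as.integer(mc_seed)),
            class = "screen_config")
}

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1,
                  BR = 1, I = 1, B = 3)

.implicit_h <- function(atoms, bonds) {
  el <- toupper(atoms$element)
  bsum <- numeric(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$i[k]] <- bsum[bonds$i[k]] + bonds$order[k]
    bsum[bonds$j[k]] <- bsum[bonds$j[k]] + bonds$order[k]
  }
  val <- .std_valence[el]
  val[is.na(val)] <- 0
  ## a positive formal charge raises the bonding capacity of N/O, a
  ## negative one lowers it (carboxylate O- carries no H)
  val <- val + atoms$charge
  pmax(0, round(val - bsum))
}

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  adj
}

.components <- function(nodes, adj) {
  comp <- list(); seen <- logical(max(c(nodes, 0L)))
  nodeset <- logical(length(seen)); nodeset[nodes] <- TRUE
  for (s in nodes) {
    if (seen[s]) next
    stack <- s; members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE; members <- c(members, v)
      for (u in adj[[v]]) if (nodeset[u] && !seen[u]) stack <- c(stack, u)
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

.lig_feature_row <- function(type, pos, dir = NULL) {
  data.frame(type = type, x = pos[1], y = pos[2], z = pos[3],
             dx = if (is.null(dir)) NA_real_ else dir[1],
             dy = if (is.null(dir)) NA_real_ else dir[2],
             dz = if (is.null(dir)) NA_real_ else dir[3],
             stringsAsFactors = FALSE)
}

## Direction away from an atom's bonded neighbours (idealized lone-pair /
## X-H bisector); +z for an unbonded atom.
.away_dir <- function(i, atoms, adj) {
  nb <- adj[[i]]
  if (!length(nb)) return(c(0, 0, 1))
  p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
  v <- c(0, 0, 0)
  for (j in nb)
    v <- v + unitv(c(atoms$x[j], atoms$y[j], atoms$z[j]) - p)
  if (vnorm(v) < 1e-9) return(c(0, 0, 1))
  -unitv(v)
}

#' Perceive pharmacophore feature points on a ligand conformer
#'
#' Deterministic structural rules: negative (`N`) features at
#' carboxylate/phosphate/sulfonate centroids or atoms with formal charge
#' <= -1; positive (`P`) at guanidinium/amidinium centroids or atoms with
#' charge >= +1; donors (`D`) at N/O bearing at least one implicit
#' hydrogen; acceptors (`A`) at N/O with a lone pair and no positive
#' charge; aromatic rings (`R`) at aromatic-system centroids with the
#' plane normal; hydrophobic (`H`) at centroids of connected
#' carbon/halogen groups of >= 2 heavy atoms outside emitted rings. Atoms
#' consumed by an ionic group are excluded from A/D perception.
#'
#' @param conformer list with `atoms` (element, x, y, z, charge) and
#'   `bonds` (i, j, order, aromatic).
#' @return data.frame of typed feature points (type, x, y, z, dx, dy, dz).
#' @export
perceive_features <- function(conformer) {
  at <- conformer$atoms; bd <- conformer$bonds
  n <- nrow(at)
  el <- toupper(at$element)
  adj <- .adjacency(n, bd)
  imp_h <- .implicit_h(at, bd)
  feats <- list()
  consumed <- logical(n)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  ## ionic groups
  for (i in which(el %in% c("C", "S", "P"))) {
    nb_o <- adj[[i]][el[adj[[i]]] == "O"]
    need <- switch(el[i], C = 2L, S = 3L, P = 3L)
    if (length(nb_o) >= need && any(at$charge[nb_o] <= -1)) {
      grp <- c(i, nb_o)
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("N", colMeans(xyz[grp, , drop = FALSE]))
      consumed[grp] <- TRUE
    }
  }
  for (i in which(el == "C")) {
    nb_n <- adj[[i]][el[adj[[i]]] == "N"]
    if (length(nb_n) >= 2L && any(at$charge[nb_n] >= 1)) {
      grp <- c(i, nb_n)
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("P", colMeans(xyz[grp, , drop = FALSE]))
      consumed[grp] <- TRUE
    }
  }
  for (i in which(!consumed & at$charge <= -1)) {
    feats[[length(feats) + 1L]] <- .lig_feature_row("N", xyz[i, ])
    consumed[i] <- TRUE
  }
  for (i in which(!consumed & at$charge >= 1)) {
    feats[[length(feats) + 1L]] <- .lig_feature_row("P", xyz[i, ])
    consumed[i] <- TRUE
  }

  ## donors and acceptors on remaining N/O
  for (i in which(!consumed & el %in% c("N", "O"))) {
    bsum <- sum(bd$order[bd$i == i | bd$j == i]) + imp_h[i]
    if (imp_h[i] >= 1)
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("D", xyz[i, ], .away_dir(i, at, adj))
    has_lp <- at$charge[i] <= 0 &&
      ((el[i] == "O") || (el[i] == "N" && bsum <= 3))
    if (has_lp)
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("A", xyz[i, ], .away_dir(i, at, adj))
  }

  ## aromatic systems
  ring_atoms <- logical(n)
  arom <- which(bd$aromatic)
  if (length(arom)) {
    sub <- bd[arom, , drop = FALSE]
    nodes <- sort(unique(c(sub$i, sub$j)))
    adj_a <- .adjacency(n, sub)
    for (comp in .components(nodes, adj_a)) {
      if (length(comp) < 3L) next
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("R", colMeans(xyz[comp, , drop = FALSE]),
                         plane_normal(xyz[comp, , drop = FALSE]))
      ring_atoms[comp] <- TRUE
    }
  }

  ## hydrophobic groups
  hydro <- which(el %in% c("C", "F", "CL", "BR", "I") & !ring_atoms & !consumed)
  if (length(hydro) >= 2L) {
    keep <- logical(n); keep[hydro] <- TRUE
    sub <- bd[keep[bd$i] & keep[bd$j], , drop = FALSE]
    adj_h <- .adjacency(n, sub)
    for (comp in .components(hydro, adj_h)) {
      if (length(comp) < 2L) next
      feats[[length(feats) + 1L]] <-
        .lig_feature_row("H", colMeans(xyz[comp, , drop = FALSE]))
    }
  }
  out <- if (length(feats)) do.call(rbind, feats) else
    .lig_feature_row("A", c(0, 0, 0))[0, ]
  rownames(out) <- NULL
  out
}

## type compatibility: model feature type -> acceptable ligand types
.compatible_types <- function(model_type) {
  switch(model_type,
         N = c("N", "A"),
         P = c("P", "D"),
         model_type)
}

## enumerate distance-consistent injective correspondences (backtracking);
## returns list of integer vectors (ligand feature index per model feature)
.enumerate_maps <- function(mpos, mtypes, lpos, ltypes, tol, cap = 5000L) {
  nm <- length(mtypes)
  dm <- as.matrix(stats::dist(mpos))
  dl <- as.matrix(stats::dist(lpos))
  cands <- lapply(mtypes, function(tt) which(ltypes %in% .compatible_types(tt)))
  maps <- list()
  assign_next <- function(k, cur) {
    if (length(maps) >= cap) return()
    if (k > nm) {
      maps[[length(maps) + 1L]] <<- cur
      return()
    }
    for (j in cands[[k]]) {
      if (j %in% cur) next
      ok <- TRUE
      for (p in seq_len(k - 1L)) {
        if (abs(dm[p, k] - dl[cur[p], j]) > tol) { ok <- FALSE; break }
      }
      if (ok) assign_next(k + 1L, c(cur, j))
    }
  }
  assign_next(1L, integer(0))
  maps
}

## Monte-Carlo fraction of the ligand vdW volume lying inside the union of
## model feature spheres. Sampling is done in the ligand's fitted frame so
## the estimate is invariant under rigid motions of the input conformer.
.volume_score <- function(lig_xyz, lig_el, model_xyz, model_tol, cfg) {
  radii <- .vdw_radius(lig_el)
  .with_seed(cfg$mc_seed, {
    npt <- cfg$mc_points
    prob <- radii^3 / sum(radii^3)
    ai <- sample.int(length(radii), npt, replace = TRUE, prob = prob)
    ## uniform in the unit ball
    u <- stats::runif(npt)^(1 / 3)
    dir <- matrix(stats::rnorm(3 * npt), npt, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pts <- lig_xyz[ai, , drop = FALSE] + dir * (u * radii[ai])
    ## multiplicity over ligand spheres -> weights for uniform-union sampling
    k <- integer(npt)
    for (a in seq_along(radii)) {
      d2 <- (pts[, 1] - lig_xyz[a, 1])^2 + (pts[, 2] - lig_xyz[a, 2])^2 +
        (pts[, 3] - lig_xyz[a, 3])^2
      k <- k + (d2 <= radii[a]^2)
    }
    w <- 1 / pmax(k, 1L)
    inside <- logical(npt)
    for (m in seq_len(nrow(model_xyz))) {
      d2 <- (pts[, 1] - model_xyz[m, 1])^2 + (pts[, 2] - model_xyz[m, 2])^2 +
        (pts[, 3] - model_xyz[m, 3])^2
      inside <- inside | d2 <= model_tol[m]^2
    }
    sum(w * inside) / sum(w)
  })
}

#' Match one ligand conformer against a pharmacophore model
#'
#' Enumerates type-compatible feature correspondences (a negative model
#' feature accepts ligand N or A points, a positive one P or D; all other
#' types match exactly), prunes them by inter-feature distance consistency
#' (every matched pair of pairs must agree within `dist_tolerance`), then
#' superposes the ligand feature points onto the model (Kabsch). The
#' alignment score is the post-fit RMSD; the vector score is the mean
#' cosine between matched direction vectors after rotation (pairs lacking
#' a direction contribute 1, and ring normals compare sign-blind since a
#' ring plane has no orientation); the volume score is the Monte-Carlo fraction
#' of the ligand's vdW volume falling inside the union of model feature
#' spheres of radius `dist_tolerance`. A match is accepted when the
#' alignment score is at most `align_reject`, the vector score at least
#' `vector_reject` and the volume score at least `volume_reject`.
#'
#' @param model `pharmacophore_model` (non-empty).
#' @param lig_features ligand feature points from [perceive_features()].
#' @param cfg [screen_config()].
#' @param lig_atoms optional conformer atom table for volume scoring; when
#'   omitted the feature points stand in for heavy atoms.
#' @return list (`MatchResult`): `correspondence`, `alignment_score`,
#'   `vector_score`, `volume_score`, `fitness`, `accepted` -- the
#'   best-fitness accepted correspondence (or, failing any accepted one,
#'   the best rejected with `accepted = FALSE`); `NULL` when no
#'   correspondence survives pruning.
#' @export
match_conformer <- function(model, lig_features, cfg = screen_config(),
                            lig_atoms = NULL) {
  mf <- model$features
  if (!nrow(mf)) stop("model is empty: no compound can be screened")
  if (!nrow(lig_features)) return(NULL)
  mpos <- as.matrix(mf[, c("x", "y", "z")])
  lpos <- as.matrix(lig_features[, c("x", "y", "z")])
  model_sets <- if (identical(cfg$min_match, "all")) {
    list(seq_len(nrow(mf)))
  } else {
    k <- max(1L, as.integer(cfg$min_match))
    unlist(lapply(seq(nrow(mf), k), function(m)
      utils::combn(nrow(mf), m, simplify = FALSE)), recursive = FALSE)
  }
  la <- if (is.null(lig_atoms))
    list(xyz = lpos, el = rep("C", nrow(lpos)))
  else list(xyz = as.matrix(lig_atoms[, c("x", "y", "z")]),
            el = lig_atoms$element)
  best <- NULL
  for (sel in model_sets) {
    maps <- .enumerate_maps(mpos[sel, , drop = FALSE], mf$type[sel],
                            lpos, lig_features$type, cfg$dist_tolerance)
    for (mp in maps) {
      fit <- kabsch_fit(lpos[mp, , drop = FALSE], mpos[sel, , drop = FALSE])
      align <- fit$rmsd
      ## vector score after rotation
      cosines <- numeric(length(sel))
      for (t in seq_along(sel)) {
        mi <- sel[t]; li <- mp[t]
        mdir <- c(mf$dx[mi], mf$dy[mi], mf$dz[mi])
        ldir <- c(lig_features$dx[li], lig_features$dy[li],
                  lig_features$dz[li])
        cosines[t] <- if (anyNA(mdir) || anyNA(ldir)) 1
        else if (mf$type[mi] == "R") abs(sum((fit$R %*% ldir) * mdir))
        else sum((fit$R %*% ldir) * mdir)
      }
      vec <- mean(cosines)
      lig_fit <- apply_rigid(la$xyz, fit$R, fit$t)
      vol <- .volume_score(lig_fit, la$el, mpos,
                           rep(cfg$dist_tolerance, nrow(mpos)), cfg)
      fitness <- cfg$w_align * (1 - align / cfg$align_reject) +
        cfg$w_vec * (vec + 1) / 2 + cfg$w_vol * vol
      accepted <- align <= cfg$align_reject && vec >= cfg$vector_reject &&
        vol >= cfg$volume_reject
      res <- list(correspondence = stats::setNames(mp, mf$id[sel]),
                  n_matched = length(sel), alignment_score = align,
                  vector_score = vec, volume_score = vol,
                  fitness = fitness, accepted = accepted)
      if (is.null(best) || (accepted && !best$accepted) ||
          (accepted == best$accepted && fitness > best$fitness))
        best <- res
    }
  }
  best
}

#' Screen a ligand library against a pharmacophore model
#'
#' For each ligand the best accepted match over its conformers is kept;
#' hits are ranked by fitness (descending, ties by ligand id). An empty
#' model screens nothing: the hit table is empty and carries the status
#' attribute `"no feature was generated, and thus no compound was
#' screened"`.
#'
#' @param model `pharmacophore_model`.
#' @param ligands list of `ligand_record`.
#' @param cfg [screen_config()].
#' @return data.frame with columns `ligand`, `conformer`, `n_matched`,
#'   `alignment_score`, `vector_score`, `volume_score`, `fitness`, `rank`;
#'   attribute `status` is `"ok"` or the empty-model status.
#' @export
screen_library <- function(model, ligands, cfg = screen_config()) {
  empty <- data.frame(ligand = character(0), conformer = integer(0),
                      n_matched = integer(0), alignment_score = numeric(0),
                      vector_score = numeric(0), volume_score = numeric(0),
                      fitness = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(model$features)) {
    warning("no feature was generated, and thus no compound was screened")
    attr(empty, "status") <- "no feature was generated, and thus no compound was screened"
    return(empty)
  }
  rows <- list()
  for (rec in ligands) {
    best <- NULL; best_cf <- NA_integer_
    for (ci in seq_along(rec$conformers)) {
      cf <- rec$conformers[[ci]]
      res <- match_conformer(model, perceive_features(cf), cfg,
                             lig_atoms = cf$atoms)
      if (!is.null(res) && res$accepted &&
          (is.null(best) || res$fitness > best$fitness)) {
        best <- res; best_cf <- ci
      }
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = rec$id, conformer = best_cf, n_matched = best$n_matched,
        alignment_score = best$alignment_score,
        vector_score = best$vector_score, volume_score = best$volume_score,
        fitness = best$fitness, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    attr(empty, "status") <- "ok"
    return(empty)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$fitness, hits$ligand), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  attr(hits, "status") <- "ok"
  hits
}
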