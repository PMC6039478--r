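## Model generation: reduce feature candidates to a screening-ready model
## (at most 8 features) and polish positions with rigid chemical probes.

#' Model-generation configuration
#'
#' @param max_features cap on the model's feature count.
#' @param refine_gate_donor donor features with enthalpy above (weaker
#'   than) this, kcal/mol, get a water-probe position polish.
#' @param refine_gate_hydrophobe hydrophobic features with enthalpy above
#'   this get a methane-probe polish; more favourable sites are left
#'   untouched.
#' @param max_displacement clamp on how far refinement may move a feature,
#'   Angstrom.
#' @param redundancy_dist hydrophobic candidates closer than this to an
#'   already-kept feature are dropped as redundant, Angstrom.
#' @param nonbonded_cutoff probe-protein interaction cutoff, Angstrom.
#' @param feature_tol tolerance radius stored on model features, Angstrom.
#' @return list of class `modelgen_config`.
#' @export
modelgen_config <- function(max_features = 8L, refine_gate_donor = -9.0,
                            refine_gate_hydrophobe = -8.2,
                            max_displacement = 1.5, redundancy_dist = 2.0,
                            nonbonded_cutoff = 8.0, feature_tol = 1.0) {
  if (max_features < 1L) stop("max_features must be at least 1")
  structure(list(max_features = as.integer(max_features),
                 refine_gate_donor = refine_gate_donor,
                 refine_gate_hydrophobe = refine_gate_hydrophobe,
                 max_displacement = max_displacement,
                 redundancy_dist = redundancy_dist,
                 nonbonded_cutoff = nonbonded_cutoff,
                 feature_tol = feature_tol),
            class = "modelgen_config")
}

#' Rigid chemical probe specification
#'
#' @param name probe name (`water`, `methane`, `acetate`, ...).
#' @param atoms data.frame: `element`, `x`, `y`, `z` (body frame, Angstrom),
#'   `charge`, `sigma`, `epsilon`.
#' @param center index of the interaction-center atom, or `"centroid"`.
#' @param net_charge expected net charge (validated against atom charges).
#' @return list of class `probe_spec`.
#' @export
probe_spec <- function(name, atoms, center = 1L, net_charge = NULL) {
  if (!is.null(net_charge) && abs(sum(atoms$charge) - net_charge) > 1e-6)
    stop("probe '", name, "' net charge ", sum(atoms$charge),
         " does not match expected ", net_charge)
  structure(list(name = name, atoms = atoms, center = center),
            class = "probe_spec")
}

#' Default probe set (water, methane, acetate)
#'
#' Parameters ship as a data file
#' (`system.file("extdata", "probes.tsv", package = "waterpharm")`):
#' TIP3P water, a united-atom methane and a 7-atom acetate with net charge
#' -1. The interaction center (flagged in the file) is the atom whose
#' refined position becomes the feature position.
#'
#' @return named list of [probe_spec()] objects.
#' @export
default_probes <- function() {
  path <- system.file("extdata", "probes.tsv", package = "waterpharm")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expected <- c(water = 0, methane = 0, acetate = -1)
  out <- list()
  for (nm in unique(tab$probe)) {
    sub <- tab[tab$probe == nm, , drop = FALSE]
    out[[nm]] <- probe_spec(nm, sub[, c("element", "x", "y", "z", "charge",
                                        "sigma", "epsilon")],
                            center = which(sub$center == 1L)[1],
                            net_charge = unname(expected[nm]))
  }
  out
}

#' Reduce feature candidates to at most `max_features`
#'
#' Priority order: ionic and polar features (`N`, `P`, `A`, `D`; ascending
#' enthalpy within type), then aromatic `R`, then hydrophobic `H` by
#' ascending enthalpy. A hydrophobic candidate lying within
#' `redundancy_dist` of an already-kept feature is dropped as redundant
#' before the count cap applies.
#'
#' @param candidates candidate data.frame ([classify_sites()] output).
#' @param cfg [modelgen_config()].
#' @return reduced candidate data.frame (possibly 0 rows, with a warning
#'   since an empty model screens nothing).
#' @export
reduce_features <- function(candidates, cfg = modelgen_config()) {
  if (!nrow(candidates)) {
    warning("no feature candidates: the model is empty and no compound ",
            "can be screened")
    return(candidates)
  }
  prio <- match(candidates$type, c("N", "P", "A", "D", "R", "H"))
  e <- candidates$E_enthalpy
  e[is.na(e)] <- Inf
  ord <- order(prio, e)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) >= cfg$max_features) break
    if (candidates$type[i] == "H" && length(kept)) {
      P <- as.matrix(candidates[kept, c("x", "y", "z")])
      d2 <- (P[, 1] - candidates$x[i])^2 + (P[, 2] - candidates$y[i])^2 +
        (P[, 3] - candidates$z[i])^2
      if (any(d2 <= cfg$redundancy_dist^2)) next
    }
    kept <- c(kept, i)
  }
  out <- candidates[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Rigid-body probe energy: probe atoms (body frame, interaction center at
## the origin) rotated by rotation vector rv and translated to pos + tv,
## against a fixed protein atom subset.
.probe_energy <- function(par, body, q, s, e, pxyz, pq, ps, pe, start) {
  R <- rotvec_matrix(par[4:6])
  lab <- t(R %*% t(body)) +
    matrix(start + par[1:3], nrow(body), 3, byrow = TRUE)
  pair_energy(lab, q, s, e, pxyz, pq, ps, pe)
}

#' Refine feature positions with rigid chemical probes
#'
#' Negative features are polished with the acetate probe; donor features
#' whose enthalpy is above (weaker than) `refine_gate_donor` with the water
#' probe; hydrophobic features above `refine_gate_hydrophobe` with the
#' methane probe. Other features, and features with no protein atom within
#' the cutoff, are untouched. Refinement is a deterministic rigid-body
#' local minimization (L-BFGS-B over translation + rotation) of the probe's
#' LJ+Coulomb energy, started at the feature position; the displacement of
#' the interaction center is clamped to `max_displacement`, and a move that
#' fails to lower the energy (or diverges) is rejected with a warning.
#'
#' @param candidates candidate data.frame with an `E_enthalpy` column.
#' @param protein `protein_structure`.
#' @param probes probe set from [default_probes()].
#' @param cfg [modelgen_config()].
#' @return the candidate data.frame with updated positions.
#' @export
refine_positions <- function(candidates, protein, probes = default_probes(),
                             cfg = modelgen_config()) {
  if (!nrow(candidates) || is.null(protein)) return(candidates)
  pa <- protein$atoms
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  for (i in seq_len(nrow(candidates))) {
    type <- candidates$type[i]
    E <- candidates$E_enthalpy[i]
    probe <- if (type == "N") probes$acetate
    else if (type == "D" && isTRUE(E > cfg$refine_gate_donor)) probes$water
    else if (type == "H" && isTRUE(E > cfg$refine_gate_hydrophobe)) probes$methane
    else NULL
    if (is.null(probe)) next
    start <- as.numeric(candidates[i, c("x", "y", "z")])
    d2 <- (pxyz[, 1] - start[1])^2 + (pxyz[, 2] - start[2])^2 +
      (pxyz[, 3] - start[3])^2
    sel <- d2 <= cfg$nonbonded_cutoff^2
    if (!any(sel)) next  # empty space: zero gradient, nothing to do
    body <- as.matrix(probe$atoms[, c("x", "y", "z")])
    ctr <- if (identical(probe$center, "centroid")) colMeans(body)
    else body[probe$center, ]
    body <- sweep(body, 2, ctr)  # interaction center at the origin
    args <- list(body = body, q = probe$atoms$charge, s = probe$atoms$sigma,
                 e = probe$atoms$epsilon, pxyz = pxyz[sel, , drop = FALSE],
                 pq = pa$charge[sel], ps = pa$sigma[sel],
                 pe = pa$epsilon[sel], start = start)
    e0 <- do.call(.probe_energy, c(list(par = rep(0, 6)), args))
    fit <- try(stats::optim(rep(0, 6), .probe_energy,
                            body = args$body, q = args$q, s = args$s,
                            e = args$e, pxyz = args$pxyz, pq = args$pq,
                            ps = args$ps, pe = args$pe, start = start,
                            method = "L-BFGS-B",
                            lower = c(rep(-cfg$max_displacement, 3), rep(-pi, 3)),
                            upper = c(rep(cfg$max_displacement, 3), rep(pi, 3))),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) {
      warning("probe refinement diverged for feature ", i,
              "; position left unchanged")
      next
    }
    par <- fit$par
    tv <- par[1:3]
    if (vnorm(tv) > cfg$max_displacement) {
      tv <- tv * (cfg$max_displacement / vnorm(tv))
      par[1:3] <- tv
    }
    e1 <- do.call(.probe_energy, c(list(par = par), args))
    if (!is.finite(e1) || e1 > e0 + 1e-9) {
      warning("probe refinement did not lower the energy for feature ", i,
              "; position left unchanged")
      next
    }
    candidates[i, c("x", "y", "z")] <- start + tv
  }
  candidates
}

#' Build a pharmacophore model from feature candidates
#'
#' Runs [reduce_features()], then [refine_positions()] (when a protein is
#' given), and serializes the result with provenance metadata including the
#' model's feature string.
#'
#' @param candidates candidate data.frame ([classify_sites()] output).
#' @param protein `protein_structure` or `NULL` to skip refinement.
#' @param cfg [modelgen_config()].
#' @param rules [feature_rules()] (recorded in metadata).
#' @param probes probe set for refinement.
#' @param target target name recorded in metadata.
#' @return [pharmacophore_model()]; empty when no candidate survives.
#' @export
build_model <- function(candidates, protein = NULL, cfg = modelgen_config(),
                        rules = feature_rules(), probes = default_probes(),
                        target = "unknown") {
  red <- reduce_features(candidates, cfg)
  red <- refine_positions(red, protein, probes, cfg)
  meta <- list(target = target,
               max_features = as.character(cfg$max_features),
               e_polar_max = as.character(rules$e_polar_max),
               ratio_low = as.character(rules$ratio_low),
               ratio_high = as.character(rules$ratio_high),
               neg_merge_dist = as.character(rules$neg_merge_dist),
               donor_positive_split = as.character(rules$donor_positive_split),
               refine_gate_donor = as.character(cfg$refine_gate_donor),
               refine_gate_hydrophobe = as.character(cfg$refine_gate_hydrophobe))
  if (!nrow(red)) {
    m <- pharmacophore_model(NULL, c(meta, list(feature_string = "")))
    return(m)
  }
  feats <- data.frame(id = sprintf("F%d", seq_len(nrow(red))),
                      type = red$type, x = red$x, y = red$y, z = red$z,
                      dx = red$dx, dy = red$dy, dz = red$dz,
                      tol = cfg$feature_tol, sites = red$sites,
                      stringsAsFactors = FALSE)
  meta$feature_string <- paste(sort(feats$type), collapse = "")
  pharmacophore_model(feats, meta)
}
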