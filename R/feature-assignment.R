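## Threshold decision tree mapping hydration-site descriptors to
## pharmacophore feature candidates, plus the acceptor-pair -> negative
## merge. All inequalities are strict: boundary equality falls through to
## the next branch.

#' Feature-assignment rules
#'
#' @param e_polar_max enthalpy gate for polar (donor/acceptor) features,
#'   kcal/mol; a site must be more favourable than this.
#' @param ratio_low,ratio_high donor/acceptor ratio gates, percent of bulk.
#' @param neg_merge_dist two acceptor features closer than this merge into
#'   one negative feature, Angstrom.
#' @param donor_positive_split mean donated H...acceptor distance above
#'   this marks a donor, below a positive feature, Angstrom.
#' @param hydrophobe_contact_radius,hydrophobe_min_contacts nonpolar
#'   protein contact proxy for hydrophobic sites (count of nonpolar atoms
#'   within the radius).
#' @param ring_dist_max,ring_normal_angle_max aromatic test: a protein ring
#'   centroid within `ring_dist_max` of the site with the centroid-to-site
#'   vector within `ring_normal_angle_max` degrees of the ring normal.
#' @return list of class `feature_rules`.
#' @export
feature_rules <- function(e_polar_max = -8.0, ratio_low = 50.0,
                          ratio_high = 100.0, neg_merge_dist = 3.5,
                          donor_positive_split = 1.5,
                          hydrophobe_contact_radius = 4.0,
                          hydrophobe_min_contacts = 6L,
                          ring_dist_max = 5.0,
                          ring_normal_angle_max = 30.0) {
  if (e_polar_max >= 0) stop("e_polar_max must be negative")
  if (ratio_low >= ratio_high) stop("ratio_low must be below ratio_high")
  structure(list(e_polar_max = e_polar_max, ratio_low = ratio_low,
                 ratio_high = ratio_high, neg_merge_dist = neg_merge_dist,
                 donor_positive_split = donor_positive_split,
                 hydrophobe_contact_radius = hydrophobe_contact_radius,
                 hydrophobe_min_contacts = hydrophobe_min_contacts,
                 ring_dist_max = ring_dist_max,
                 ring_normal_angle_max = ring_normal_angle_max),
            class = "feature_rules")
}

.candidate_row <- function(type, pos, dir, site) {
  data.frame(type = type, x = pos[1], y = pos[2], z = pos[3],
             dx = if (is.null(dir)) NA_real_ else dir[1],
             dy = if (is.null(dir)) NA_real_ else dir[2],
             dz = if (is.null(dir)) NA_real_ else dir[3],
             sites = paste(site, collapse = ","),
             E_enthalpy = NA_real_, acceptor_ratio = NA_real_,
             donor_ratio = NA_real_, mean_donor_H_dist = NA_real_,
             stringsAsFactors = FALSE)
}

#' Classify a hydration site as a pharmacophore feature candidate
#'
#' Decision tree, evaluated in order:
#' 1. donor branch: `E < e_polar_max`, acceptor ratio `< ratio_low`,
#'    donor ratio `> ratio_high` -> `D` if the mean donated H...acceptor
#'    distance exceeds `donor_positive_split`, else `P`;
#' 2. acceptor branch: `E < e_polar_max`, acceptor ratio `> ratio_high`,
#'    donor ratio `< ratio_low` -> `A`;
#' 3. apolar branch (both ratios `< ratio_high`): `R` if a protein aromatic
#'    ring passes the geometric test, else `H` if enough nonpolar protein
#'    contacts, else nothing;
#' 4. otherwise nothing.
#'
#' Direction vectors: `D` along the mean donated O->H direction, `A` from
#' the mean accepted partner toward the site, `R` the matched ring normal.
#'
#' @param site `hydration_site` carrying descriptors.
#' @param protein `protein_structure` (rings + nonpolar contacts).
#' @param rules [feature_rules()].
#' @return one-row candidate data.frame, or `NULL` when no feature applies.
#' @export
classify_site <- function(site, protein, rules = feature_rules()) {
  E <- site$E_enthalpy; ar <- site$acceptor_ratio; dr <- site$donor_ratio
  ctr <- site$center
  polar_ok <- E < rules$e_polar_max
  if (polar_ok && ar < rules$ratio_low && dr > rules$ratio_high) {
    if (isTRUE(site$mean_donor_H_dist > rules$donor_positive_split)) {
      dir <- site$donated_dir
      if (anyNA(dir)) dir <- c(0, 0, 1)
      return(.candidate_snapshot(.candidate_row("D", ctr, unitv(dir), site$id), site))
    }
    return(.candidate_snapshot(.candidate_row("P", ctr, NULL, site$id), site))
  }
  if (polar_ok && ar > rules$ratio_high && dr < rules$ratio_low)
    return(.candidate_snapshot(.candidate_row("A", ctr, .acc_dir(site), site$id), site))
  if (ar < rules$ratio_high && dr < rules$ratio_high) {
    ring <- .match_ring(ctr, protein, rules)
    if (!is.null(ring))
      return(.candidate_snapshot(.candidate_row("R", ctr, ring, site$id), site))
    if (.nonpolar_contacts(ctr, protein, rules$hydrophobe_contact_radius) >=
        rules$hydrophobe_min_contacts)
      return(.candidate_snapshot(.candidate_row("H", ctr, NULL, site$id), site))
  }
  NULL
}

.candidate_snapshot <- function(row, site) {
  row$E_enthalpy <- site$E_enthalpy
  row$acceptor_ratio <- site$acceptor_ratio
  row$donor_ratio <- site$donor_ratio
  row$mean_donor_H_dist <- site$mean_donor_H_dist %||% NA_real_
  row
}

.acc_dir <- function(site) {
  dir <- site$accepted_dir
  if (is.null(dir) || anyNA(dir)) c(0, 0, 1) else unitv(dir)
}

.match_ring <- function(center, protein, rules) {
  rings <- protein$rings
  if (is.null(rings) || !nrow(rings)) return(NULL)
  for (i in seq_len(nrow(rings))) {
    ctr <- c(rings$cx[i], rings$cy[i], rings$cz[i])
    v <- center - ctr
    d <- vnorm(v)
    if (d > rules$ring_dist_max || d < 1e-9) next
    nrm <- c(rings$nx[i], rings$ny[i], rings$nz[i])
    cosang <- abs(sum(v / d * nrm))  # ring normal sign is arbitrary
    if (cosang >= cos(rules$ring_normal_angle_max * pi / 180))
      return(nrm * sign(sum(v * nrm)))  # normal oriented toward the site
  }
  NULL
}

.nonpolar_contacts <- function(center, protein, radius) {
  pa <- protein$atoms
  np <- pa[pa$polarity == "nonpolar", , drop = FALSE]
  if (!nrow(np)) return(0L)
  d2 <- (np$x - center[1])^2 + (np$y - center[2])^2 + (np$z - center[3])^2
  sum(d2 <= radius^2)
}

#' Classify every site of a hydration-site list
#'
#' Applies [classify_site()] to each site and then [merge_negatives()].
#'
#' @param sites `hydration_site_list`.
#' @param protein `protein_structure`.
#' @param rules [feature_rules()].
#' @param merge merge close acceptor pairs into negatives (default TRUE).
#' @return candidate data.frame (possibly 0 rows).
#' @export
classify_sites <- function(sites, protein, rules = feature_rules(),
                           merge = TRUE) {
  rows <- Filter(Negate(is.null),
                 lapply(sites, classify_site, protein = protein, rules = rules))
  cands <- if (length(rows)) do.call(rbind, rows) else
    .candidate_row("A", c(0, 0, 0), c(0, 0, 1), "x")[0, ]
  rownames(cands) <- NULL
  if (merge) merge_negatives(cands, rules) else cands
}

#' Merge close acceptor pairs into negative features
#'
#' Among `A` candidates, the closest pair within `neg_merge_dist` is
#' replaced by one `N` feature at the pair midpoint; this repeats greedily
#' until no pair qualifies. Each acceptor is consumed at most once and
#' non-acceptor candidates pass through untouched.
#'
#' @param candidates candidate data.frame (from [classify_site()] rows).
#' @param rules [feature_rules()].
#' @return candidate data.frame with merges applied.
#' @export
merge_negatives <- function(candidates, rules = feature_rules()) {
  if (!nrow(candidates)) return(candidates)
  out <- candidates
  repeat {
    a_idx <- which(out$type == "A")
    if (length(a_idx) < 2L) break
    P <- as.matrix(out[a_idx, c("x", "y", "z")])
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    m <- which(D == min(D), arr.ind = TRUE)[1, ]
    if (D[m[1], m[2]] > rules$neg_merge_dist) break
    i <- a_idx[min(m)]; j <- a_idx[max(m)]
    mid <- (as.numeric(out[i, c("x", "y", "z")]) +
              as.numeric(out[j, c("x", "y", "z")])) / 2
    nrow_new <- .candidate_row("N", mid, NULL,
                               c(out$sites[i], out$sites[j]))
    nrow_new$E_enthalpy <- min(out$E_enthalpy[i], out$E_enthalpy[j])
    out <- rbind(out[-c(i, j), , drop = FALSE], nrow_new)
    rownames(out) <- NULL
  }
  out
}
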