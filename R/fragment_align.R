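#' @title Fragment transformation alignment
#' @name fragment_align
#' @description
#' The alignment core: least-squares rigid superposition of backbone
#' N-CA-C triplets, the m x n grid of query-to-template transforms, and
#' single-linkage clustering of mutually consistent triplet pairs into
#' aligned substructures.
NULL

#' Rigid superposition of one triplet onto another
#'
#' Least-squares rotation + translation (no reflection) mapping the three
#' ordered atoms of `sigma` onto `tau`.
#'
#' @param sigma,tau 3x3 triplet matrices (rows N, CA, C).
#' @return a `rigid_transform`: `list(rotation, translation, residual)`
#'   where `residual` is the 3-atom RMSD of the mapped `sigma` vs `tau`.
#' @export
superpose_triplet <- function(sigma, tau) {
  stopifnot(is.matrix(sigma), is.matrix(tau),
            all(dim(sigma) == c(3, 3)), all(dim(tau) == c(3, 3)))
  for (trip in list(sigma, tau)) {
    v1 <- trip[2, ] - trip[1, ]
    v2 <- trip[3, ] - trip[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (vec_norm(cr) < 1e-6) stop("degenerate (collinear) triplet")
  }
  res <- .kabsch3_cpp(sigma, tau)
  structure(list(rotation = res$rotation,
                 translation = as.numeric(res$translation),
                 residual = res$residual),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param x an n x 3 coordinate matrix or length-3 vector.
#' @return transformed coordinates with the shape of `x`.
#' @export
apply_transform <- function(transform, x) {
  if (is.null(dim(x))) {
    as.numeric(transform$rotation %*% x + transform$translation)
  } else {
    t(transform$rotation %*% t(x) + transform$translation)
  }
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  structure(list(rotation = Rt,
                 translation = as.numeric(-Rt %*% transform$translation),
                 residual = NA_real_),
            class = "rigid_transform")
}

#' Transform-consistency distance between triplet pairs
#'
#' \eqn{D_{kl}^{ij}}: the 3-atom RMSD between `sigma_k` carried through
#' pair (i,j)'s transform and the target `tau_l`.  Callers symmetrize as
#' the max of the two directions.
#'
#' @param pair_a a `rigid_transform` (the transform of pair (i,j)).
#' @param sigma_k,tau_l triplet matrices of the other pair.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(pair_a, sigma_k, tau_l) {
  .pair_distance_cpp(pair_a$rotation, pair_a$translation, sigma_k, tau_l)
}

# union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Cluster the triplet-pair grid by single linkage
#'
#' Builds all query x template triplet pairs (dropping pairs whose
#' superposition residual exceeds `resid_max`), joins two pairs when they
#' involve distinct query and distinct template residues and their
#' symmetrized transform-consistency distance is below `d0`, and takes
#' connected components.  Within each component one-to-one conflicts are
#' resolved greedily by ascending residual (ties by (i, j) order); the
#' representative transform is the member transform with the smallest
#' total symmetrized distance to the other members.
#'
#' @param query_triplets list of query triplets (or output of
#'   [extract_triplets()]).
#' @param template a template (list with `residues` carrying triplets) or
#'   a plain list of triplet matrices.
#' @param d0 single-linkage distance threshold in Angstrom (default 2.0).
#' @param min_size minimum cluster size (default 2).
#' @param resid_max residual pre-filter for grid nodes (default 0.5).
#' @return list of `cluster_alignment`s: each has `pairs` (data.frame
#'   `qi`, `tj`, `residual`), `transforms`, `rep_transform`, `rep_pair`,
#'   `s_mu`/`t_mu` (query/template triplet indices), `epsilon`, `rmsd_ca`.
#' @export
cluster_triplet_pairs <- function(query_triplets, template, d0 = 2.0,
                                  min_size = 2L, resid_max = 0.5) {
  stopifnot(d0 > 0)
  tpl_triplets <- if (!is.null(template$residues)) {
    lapply(template$residues, `[[`, "triplet")
  } else {
    template
  }
  if (length(tpl_triplets) < 2) stop("template must have at least 2 triplets")
  qm <- triplets_to_matrix(query_triplets)
  tm <- triplets_to_matrix(tpl_triplets)
  g <- .grid_align_cpp(qm, tm, d0, resid_max)
  K <- length(g$qi)
  if (K == 0) return(list())
  # connected components over the edge list
  parent <- seq_len(K)
  for (e in seq_along(g$edge_a)) {
    ra <- uf_find(parent, g$edge_a[e])
    rb <- uf_find(parent, g$edge_b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(K), function(i) uf_find(parent, i), integer(1))
  clusters <- list()
  for (root in unique(roots)) {
    members <- which(roots == root)
    if (length(members) < 2) next
    # greedy one-to-one resolution: ascending residual, then (i, j)
    ord <- members[order(g$residual[members], g$qi[members], g$tj[members])]
    used_q <- integer(0); used_t <- integer(0); sel <- integer(0)
    for (a in ord) {
      if (g$qi[a] %in% used_q || g$tj[a] %in% used_t) next
      sel <- c(sel, a)
      used_q <- c(used_q, g$qi[a]); used_t <- c(used_t, g$tj[a])
    }
    if (length(sel) < max(2L, min_size)) next
    sel <- sel[order(g$qi[sel])]
    transforms <- lapply(sel, function(a) {
      structure(list(rotation = g$rotations[, , a],
                     translation = as.numeric(g$translations[, a]),
                     residual = g$residual[a]),
                class = "rigid_transform")
    })
    # representative: minimal total symmetrized distance to the others
    nsel <- length(sel)
    tot <- numeric(nsel)
    for (a in seq_len(nsel)) {
      for (b in seq_len(nsel)) {
        if (a == b) next
        d1 <- pair_distance(transforms[[a]],
                            query_triplets[[g$qi[sel[b]]]],
                            tpl_triplets[[g$tj[sel[b]]]])
        d2 <- pair_distance(transforms[[b]],
                            query_triplets[[g$qi[sel[a]]]],
                            tpl_triplets[[g$tj[sel[a]]]])
        tot[a] <- tot[a] + max(d1, d2)
      }
    }
    rep_idx <- which.min(tot)
    cl <- structure(list(
      pairs = data.frame(qi = g$qi[sel], tj = g$tj[sel],
                         residual = g$residual[sel]),
      transforms = transforms,
      rep_transform = transforms[[rep_idx]],
      rep_pair = c(qi = g$qi[sel[rep_idx]], tj = g$tj[sel[rep_idx]]),
      s_mu = g$qi[sel], t_mu = g$tj[sel],
      epsilon = nsel, rmsd_ca = NA_real_
    ), class = "cluster_alignment")
    cl$rmsd_ca <- cluster_rmsd_ca(cl, query_triplets, tpl_triplets)
    clusters[[length(clusters) + 1L]] <- cl
  }
  clusters
}

#' C-alpha RMSD of an aligned substructure pair
#'
#' RMSD of the query CA atoms mapped through the cluster's representative
#' transform against the matched template CA atoms.
#'
#' @param cluster a `cluster_alignment`.
#' @param query_triplets,template_triplets the triplet lists the cluster
#'   was built from.
#' @return RMSD in Angstrom.
#' @export
cluster_rmsd_ca <- function(cluster, query_triplets, template_triplets) {
  if (!is.matrix(template_triplets[[1]])) {
    template_triplets <- lapply(template_triplets, `[[`, "triplet")
  }
  tr <- cluster$rep_transform
  ss <- 0
  n <- length(cluster$s_mu)
  for (k in seq_len(n)) {
    qca <- apply_transform(tr, query_triplets[[cluster$s_mu[k]]]["CA", ])
    tca <- template_triplets[[cluster$t_mu[k]]]["CA", ]
    ss <- ss + sum((qca - tca)^2)
  }
  sqrt(ss / n)
}
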