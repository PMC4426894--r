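#' @title Synthetic structures and planted binding sites
#' @name synthetic_fixtures
#' @description
#' Deterministic, download-free test inputs: ideal-geometry backbones,
#' binding sites planted by copying template triplets under a random rigid
#' motion with controllable Gaussian coordinate noise, pseudo-ligands with
#' known moiety centers, and complete toy datasets that exercise the full
#' pipeline through its real file readers.
NULL

# Ideal backbone geometry (bond lengths in Angstrom, angles in degrees).
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  omega = 180
)

# phi/psi (degrees) per secondary-structure symbol
SS_DIHEDRALS <- list(
  H = c(phi = -57, psi = -47),
  E = c(phi = -119, psi = 113),
  `-` = c(phi = -140, psi = 155)
)

# place atom d from a, b, c with given bond length |cd|, angle b-c-d and
# torsion a-b-c-d (natural extension reference frame)
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vec_norm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

residue_from_triplet <- function(trip, chain_id, seq_pos, res_name, ss = "-") {
  list(chain_id = chain_id, seq_pos = seq_pos, icode = "",
       seq_key = as.character(seq_pos), res_name = res_name,
       one_letter = residue_one_letter(res_name),
       atoms = data.frame(name = c("N", "CA", "C"),
                          element = c("N", "C", "C"),
                          x = trip[, "x"], y = trip[, "y"], z = trip[, "z"]),
       triplet = trip, ss = ss)
}

#' Generate an ideal-geometry backbone chain
#'
#' Builds N-CA-C coordinates from ideal bond lengths and angles with
#' trans peptide bonds and phi/psi fixed per secondary-structure symbol:
#' (-57, -47) for H, (-119, 113) for E and (-140, 155) for coil.  A pure
#' function of its arguments (and `seed`, used only when `sequence` is
#' not supplied).
#'
#' @param n_residues chain length.
#' @param ss_pattern string over H/E/- of length `n_residues` (default all
#'   helix).
#' @param sequence one-letter amino-acid string (default: random, drawn
#'   with `seed`).
#' @param seed RNG seed for the random sequence.
#' @param chain_id chain identifier, default "A".
#' @return list of residue units.
#' @export
generate_ideal_backbone <- function(n_residues, ss_pattern = NULL,
                                    sequence = NULL, seed = 1L,
                                    chain_id = "A") {
  stopifnot(n_residues >= 1)
  if (is.null(ss_pattern)) ss_pattern <- strrep("H", n_residues)
  ss <- strsplit(ss_pattern, "")[[1]]
  if (length(ss) != n_residues) stop("ss_pattern length must equal n_residues")
  if (!all(ss %in% c("H", "E", "-"))) {
    stop("invalid ss symbol(s): ", paste(setdiff(ss, c("H", "E", "-")), collapse = ""))
  }
  aa1 <- names(AA3TO1)
  if (is.null(sequence)) {
    set.seed(seed)
    seq3 <- sample(aa1, n_residues, replace = TRUE)
  } else {
    letters1 <- strsplit(sequence, "")[[1]]
    if (length(letters1) != n_residues) stop("sequence length must equal n_residues")
    rev_map <- stats::setNames(names(AA3TO1), AA3TO1)
    seq3 <- rev_map[letters1]
    if (anyNA(seq3)) stop("unknown amino-acid letter in sequence")
  }
  g <- IDEAL_GEOM
  phi <- vapply(ss, function(s) SS_DIHEDRALS[[s]]["phi"], numeric(1))
  psi <- vapply(ss, function(s) SS_DIHEDRALS[[s]]["psi"], numeric(1))
  coords <- vector("list", n_residues)
  # first residue in a canonical frame
  n1 <- c(0, 0, 0)
  ca1 <- c(g$b_n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  c1 <- ca1 + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  coords[[1]] <- new_triplet(n1, ca1, c1)
  for (i in seq_len(n_residues - 1L)) {
    prev <- coords[[i]]
    n_next <- nerf_place(prev["N", ], prev["CA", ], prev["C", ],
                         g$b_c_n, g$ang_ca_c_n, psi[i])
    ca_next <- nerf_place(prev["CA", ], prev["C", ], n_next,
                          g$b_n_ca, g$ang_c_n_ca, g$omega)
    c_next <- nerf_place(prev["C", ], n_next, ca_next,
                         g$b_ca_c, g$ang_n_ca_c, phi[i + 1])
    coords[[i + 1L]] <- new_triplet(n_next, ca_next, c_next)
  }
  lapply(seq_len(n_residues), function(i) {
    residue_from_triplet(coords[[i]], chain_id, i, seq3[i], ss[i])
  })
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Plant template-matching binding sites into a chain
#'
#' Overwrites randomly chosen chain positions with the triplets, residue
#' names and secondary-structure labels of one or more templates after a
#' single random rigid motion (shared across templates so inter-moiety
#' geometry is preserved) plus iid Gaussian coordinate noise.  The
#' templates' ligand centers are transported by the same motion and
#' recorded as ground truth.
#'
#' @param chain list of residue units.
#' @param templates one template or a list (each with `residues`, `moiety`
#'   and `ligand_center`).
#' @param noise_sigma Gaussian noise standard deviation per coordinate, in
#'   Angstrom.
#' @param seed RNG seed.
#' @param displacement distance from the chain centroid at which the site
#'   is placed (keeps decoy residues away), default 30 Angstrom.
#' @return list with `chain`, `positions` (list per template),
#'   `true_centers` (moiety -> transported center), `rotation`,
#'   `translation`.
#' @export
plant_binding_site <- function(chain, templates, noise_sigma = 0, seed = 1L,
                               displacement = 30) {
  if (!is.null(templates$residues)) templates <- list(templates)
  total <- sum(vapply(templates, function(t) length(t$residues), integer(1)))
  if (length(chain) < total + 4) stop("template larger than chain allows")
  stopifnot(noise_sigma >= 0)
  set.seed(seed)
  R <- random_rotation()
  all_coords <- do.call(rbind, unlist(lapply(templates, function(t) {
    lapply(t$residues, function(r) r$triplet)
  }), recursive = FALSE))
  site_centroid <- colMeans(all_coords)
  chain_centroid <- colMeans(do.call(rbind, lapply(chain, function(r) r$triplet["CA", , drop = FALSE])))
  dir <- rnorm(3); dir <- dir / vec_norm(dir)
  tvec <- unname(chain_centroid + displacement * dir - as.numeric(R %*% site_centroid))
  pos_pool <- sample(seq_along(chain), total)
  positions <- list()
  true_centers <- list()
  off <- 0L
  for (t_idx in seq_along(templates)) {
    tpl <- templates[[t_idx]]
    k <- length(tpl$residues)
    pos <- sort(pos_pool[(off + 1L):(off + k)])
    off <- off + k
    for (j in seq_len(k)) {
      r <- tpl$residues[[j]]
      trip <- t(R %*% t(r$triplet)) + matrix(tvec, 3, 3, byrow = TRUE)
      if (noise_sigma > 0) trip <- trip + matrix(rnorm(9, 0, noise_sigma), 3, 3)
      trip <- new_triplet(trip[1, ], trip[2, ], trip[3, ])
      i <- pos[j]
      chain[[i]] <- residue_from_triplet(trip, chain[[i]]$chain_id,
                                         chain[[i]]$seq_pos, r$res_name,
                                         r$ss %||% "-")
    }
    positions[[t_idx]] <- vapply(pos, function(i) chain[[i]]$seq_key, character(1))
    true_centers[[tpl$moiety]] <- as.numeric(R %*% tpl$ligand_center) + tvec
  }
  names(positions) <- vapply(templates, `[[`, character(1), "moiety")
  list(chain = chain, positions = positions, true_centers = true_centers,
       rotation = R, translation = tvec)
}

# Pseudo-ligand atom names per moiety: 4-atom subsets of the NAD partition
# table so the real partition code path is exercised.
PSEUDO_LIGAND_ATOMS <- list(
  nicotinamide = c("N1N", "C2N", "C3N", "C7N"),
  adenosine = c("N9A", "C8A", "N7A", "C5A"),
  phosphate = c("PA", "O1A", "O2A", "O3")
)

pseudo_atom_offsets <- function(spread = 0.6) {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * spread / sqrt(3)
}

# Build one master binding site: three moieties with centers 4-8 Angstrom
# apart, each moiety a set of independently oriented triplets whose CA
# atoms sit ~2.9 Angstrom from the moiety center (and away from the other
# moieties).
make_master_site <- function(sizes = NULL, radius = 2.9) {
  moieties <- names(PSEUDO_LIGAND_ATOMS)
  if (is.null(sizes)) {
    sizes <- stats::setNames(sample(2:6, 3, replace = TRUE), moieties)
  }
  repeat {
    d <- runif(3, 4, 8) # pairwise center distances
    if (d[1] + d[2] > d[3] && d[1] + d[3] > d[2] && d[2] + d[3] > d[1]) break
  }
  c1 <- c(0, 0, 0)
  c2 <- c(d[1], 0, 0)
  x3 <- (d[1]^2 + d[2]^2 - d[3]^2) / (2 * d[1])
  y3 <- sqrt(max(0, d[2]^2 - x3^2))
  centers <- list(c1, c2, c(x3, y3, 0))
  names(centers) <- moieties
  base_names <- c("GLY", "SER", "THR", "ARG", "HIS", "TYR", "ASP",
                  "ASN", "TRP", "PHE", "CYS", "ILE")
  ideal <- generate_ideal_backbone(1, "-")[[1]]$triplet
  ideal <- ideal - matrix(colMeans(ideal), 3, 3, byrow = TRUE)
  templates <- list()
  for (m in moieties) {
    ctr <- centers[[m]]
    others <- setdiff(moieties, m)
    residues <- list()
    for (j in seq_len(sizes[[m]])) {
      repeat {
        Rr <- random_rotation()
        u <- rnorm(3); u <- u / vec_norm(u)
        trip <- t(Rr %*% t(ideal))
        ca_target <- ctr + radius * u
        trip <- trip + matrix(ca_target - trip[2, ], 3, 3, byrow = TRUE)
        far_enough <- all(vapply(others, function(o) {
          min(sqrt(rowSums((trip - matrix(centers[[o]], 3, 3, byrow = TRUE))^2))) > 4.5
        }, logical(1)))
        if (far_enough) break
      }
      rn <- sample(base_names, 1)
      residues[[j]] <- list(res_name = rn, one_letter = residue_one_letter(rn),
                            ss = "-", triplet = new_triplet(trip[1, ], trip[2, ], trip[3, ]))
    }
    templates[[m]] <- list(moiety = m, residues = residues, ligand_center = ctr)
  }
  list(templates = templates, centers = centers)
}

#' Serialize a structure model as PDB text
#'
#' Writes ATOM records for the protein chains and HETATM records for the
#' ligands (coordinates at the format's 3-decimal precision).
#'
#' @param model a `structure_model`.
#' @param path optional output file.
#' @return the PDB lines, invisibly when `path` is given.
#' @export
write_pdb_model <- function(model, path = NULL) {
  lines <- sprintf("%-62s%4s", "HEADER", toupper(substr(model$pdb_id, 1, 4)))
  serial <- 0L
  fmt <- function(rec, serial, name, res, chain, seq, x, y, z, element) {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, nm, res, chain, seq, x, y, z, 1.0, 0.0, element)
  }
  for (cid in names(model$chains)) {
    for (r in model$chains[[cid]]) {
      for (k in seq_len(nrow(r$atoms))) {
        serial <- serial + 1L
        a <- r$atoms[k, ]
        lines <- c(lines, fmt("ATOM", serial, a$name, r$res_name, cid,
                              r$seq_pos, a$x, a$y, a$z, a$element))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %-3s %s", serial + 1L,
                              model$chains[[cid]][[length(model$chains[[cid]])]]$res_name, cid))
  }
  for (lig in model$ligands) {
    for (k in seq_len(nrow(lig$atoms))) {
      serial <- serial + 1L
      a <- lig$atoms[k, ]
      lines <- c(lines, fmt("HETATM", serial, a$name, lig$ligand_code,
                            lig$chain_id, lig$het_seq, a$x, a$y, a$z, a$element))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Generate a complete toy benchmark dataset
#'
#' `n_proteins` ideal-backbone chains of 60-120 residues, each carrying a
#' noisy planted copy (per-protein noise sigma drawn from
#' `noise_range`) of one shared three-moiety binding site whose moiety
#' centers lie 4-8 Angstrom apart, plus a 12-atom pseudo-NAD whose atom
#' names match the real moiety partition table.  Templates are rebuilt
#' from the generated models through the regular template-construction
#' path.
#'
#' @param n_proteins number of proteins (>= 2).
#' @param params list; honoured entries `sizes` (named moiety sizes),
#'   `noise_range` (default `c(0.1, 0.5)`), `cutoff` (default 3.5).
#' @param seed RNG seed driving every random choice.
#' @return list with `entries` (each `list(model, annotations,
#'   true_centers, noise_sigma, planted)`) and `db` (a
#'   `template_database`).
#' @export
make_toy_dataset <- function(n_proteins, params = list(), seed = 42L) {
  stopifnot(n_proteins >= 2)
  noise_range <- params$noise_range %||% c(0.1, 0.5)
  set.seed(seed)
  master <- make_master_site(sizes = params$sizes)
  offsets <- pseudo_atom_offsets()
  entries <- list()
  for (pidx in seq_len(n_proteins)) {
    n_res <- sample(60:120, 1)
    ss <- character(0)
    while (length(ss) < n_res) {
      ss <- c(ss, rep(sample(c("H", "E", "-"), 1, prob = c(0.45, 0.3, 0.25)),
                      sample(3:12, 1)))
    }
    ss <- paste(ss[seq_len(n_res)], collapse = "")
    chain <- generate_ideal_backbone(n_res, ss, seed = sample.int(2^31 - 1, 1))
    sigma <- runif(1, noise_range[1], noise_range[2])
    planted <- plant_binding_site(chain, master$templates, noise_sigma = sigma,
                                  seed = sample.int(2^31 - 1, 1))
    # pseudo-ligand: 4 atoms per moiety around each transported center
    lig_rows <- list()
    for (m in names(PSEUDO_LIGAND_ATOMS)) {
      ctr <- planted$true_centers[[m]]
      nm <- PSEUDO_LIGAND_ATOMS[[m]]
      for (k in 1:4) {
        lig_rows[[length(lig_rows) + 1L]] <- data.frame(
          name = nm[k], element = substr(nm[k], 1, 1),
          x = ctr[1] + offsets[k, 1], y = ctr[2] + offsets[k, 2],
          z = ctr[3] + offsets[k, 3], stringsAsFactors = FALSE)
      }
    }
    pdb_id <- sprintf("s%03d", pidx)
    model <- structure(list(
      pdb_id = pdb_id,
      chains = list(A = planted$chain),
      ligands = list(list(ligand_code = "NAD", chain_id = "A", het_seq = 900L,
                          atoms = do.call(rbind, lig_rows)))
    ), class = "structure_model")
    ann <- list(pdb_id = pdb_id, chain_id = "A", ligand_code = "NAD",
                binding_positions = unname(unlist(planted$positions)))
    entries[[pidx]] <- list(model = model, annotations = list(ann),
                            true_centers = planted$true_centers,
                            planted = planted$positions, noise_sigma = sigma)
  }
  models <- lapply(entries, function(e) {
    m <- e$model
    apply_ss_labels(m, assign_secondary_structure(m))
  })
  db <- build_template_db(models, params = list(cutoff = params$cutoff %||% 3.5))
  list(entries = entries, db = db)
}

#' A small full-atom-name NAD ligand fixture
#'
#' All 44 heavy-atom names of the partition table placed near their
#' moiety centers; used to exercise the partition on a complete ligand.
#'
#' @param centers named list of three moiety centers (defaults roughly
#'   7 Angstrom apart).
#' @return a ligand instance.
#' @export
synthetic_full_nad <- function(centers = list(
    nicotinamide = c(0, 0, 0), adenosine = c(12, 0, 0), phosphate = c(6, 3, 0))) {
  part <- moiety_partition("NAD")
  rows <- list()
  for (m in names(part)) {
    nms <- part[[m]]
    for (k in seq_along(nms)) {
      ang <- 2 * pi * k / length(nms)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nms[k], element = substr(gsub("[0-9']", "", nms[k]), 1, 1),
        x = centers[[m]][1] + 1.2 * cos(ang),
        y = centers[[m]][2] + 1.2 * sin(ang),
        z = centers[[m]][3], stringsAsFactors = FALSE)
    }
  }
  list(ligand_code = "NAD", chain_id = "A", het_seq = 500L,
       atoms = do.call(rbind, rows))
}
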