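# Shared fixture builders and independent oracles.

# a non-degenerate triplet with roughly peptide-like internal geometry
base_triplet <- function() {
  rbind(N = c(-1.458, 0, 0),
        CA = c(0, 0, 0),
        C = c(0.552, 1.421, 0))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigidly_move <- function(trip, R, t) {
  out <- t(R %*% t(trip)) + matrix(t, 3, 3, byrow = TRUE)
  rownames(out) <- rownames(trip)
  colnames(out) <- c("x", "y", "z")
  out
}

random_triplet <- function(jitter = 0.2, box = 20) {
  trip <- base_triplet() + matrix(rnorm(9, 0, jitter), 3, 3)
  rigidly_move(trip, random_rotation_matrix(), runif(3, -box, box))
}

# minimal PDB ATOM line (fixed columns)
pdb_atom_line <- function(serial, name, res, chain, seq, xyz, rec = "ATOM",
                          alt = " ", occ = 1.0, element = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, res, chain, seq, xyz[1], xyz[2], xyz[3],
          occ, 0.0, element)
}

gly_residue_pdb <- function(seq = 1, chain = "A", shift = c(0, 0, 0),
                            serial0 = 0) {
  trip <- base_triplet() + matrix(shift, 3, 3, byrow = TRUE)
  c(pdb_atom_line(serial0 + 1, "N", "GLY", chain, seq, trip[1, ]),
    pdb_atom_line(serial0 + 2, "CA", "GLY", chain, seq, trip[2, ]),
    pdb_atom_line(serial0 + 3, "C", "GLY", chain, seq, trip[3, ]))
}

# classic-format DSSP text: resnum cols 6-10, icode 11, chain 12, AA 14, SS 17
dssp_text <- function(chain, nums, aa, ss) {
  hdr <- c("==== Secondary Structure Definition, synthetic ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- vapply(seq_along(nums), function(i) {
    sprintf("%5d%5d %s %s  %s", i, nums[i], chain, aa[i], ss[i])
  }, character(1))
  paste(c(hdr, body), collapse = "\n")
}

# independent confusion-metric implementation (oracle)
oracle_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  mcc_num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  list(acc = (tp + tn) / n,
       tpr = tp / (tp + fn),
       fpr = fp / (fp + tn),
       mcc = if (mcc_den == 0) 0 else mcc_num / mcc_den)
}

# brute-force single-linkage oracle over the triplet-pair grid
oracle_cluster <- function(qtrips, ttrips, d0 = 2.0, min_size = 2L,
                           resid_max = 0.5) {
  grid <- list()
  for (i in seq_along(qtrips)) {
    for (j in seq_along(ttrips)) {
      tr <- superpose_triplet(qtrips[[i]], ttrips[[j]])
      if (tr$residual <= resid_max) {
        grid[[length(grid) + 1L]] <- list(i = i, j = j, tr = tr)
      }
    }
  }
  K <- length(grid)
  if (K == 0) return(list())
  A <- matrix(FALSE, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a == b) next
      ga <- grid[[a]]; gb <- grid[[b]]
      if (ga$i == gb$i || ga$j == gb$j) next
      d <- max(pair_distance(ga$tr, qtrips[[gb$i]], ttrips[[gb$j]]),
               pair_distance(gb$tr, qtrips[[ga$i]], ttrips[[ga$j]]))
      A[a, b] <- d < d0
    }
  }
  # transitive closure
  reach <- A | diag(TRUE, K)
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp_id <- rep(NA_integer_, K)
  cid <- 0L
  for (a in seq_len(K)) {
    if (is.na(comp_id[a])) {
      cid <- cid + 1L
      comp_id[which(reach[a, ])] <- cid
    }
  }
  out <- list()
  for (cc in unique(comp_id)) {
    members <- which(comp_id == cc)
    if (length(members) < 2) next
    resids <- vapply(members, function(a) grid[[a]]$tr$residual, numeric(1))
    is <- vapply(members, function(a) grid[[a]]$i, integer(1))
    js <- vapply(members, function(a) grid[[a]]$j, integer(1))
    ord <- order(resids, is, js)
    used_i <- integer(0); used_j <- integer(0); sel <- integer(0)
    for (a in members[ord]) {
      if (grid[[a]]$i %in% used_i || grid[[a]]$j %in% used_j) next
      sel <- c(sel, a)
      used_i <- c(used_i, grid[[a]]$i); used_j <- c(used_j, grid[[a]]$j)
    }
    if (length(sel) < max(2L, min_size)) next
    pr <- cbind(i = vapply(sel, function(a) grid[[a]]$i, integer(1)),
                j = vapply(sel, function(a) grid[[a]]$j, integer(1)))
    out[[length(out) + 1L]] <- pr[order(pr[, 1]), , drop = FALSE]
  }
  out
}

# canonical string form of a clustering for comparison
cluster_signature <- function(clusters) {
  sigs <- vapply(clusters, function(cl) {
    if (is.matrix(cl)) {
      paste(cl[, 1], cl[, 2], sep = ":", collapse = ",")
    } else {
      paste(cl$s_mu, cl$t_mu, sep = ":", collapse = ",")
    }
  }, character(1))
  sort(sigs)
}

# random clustering instance: template = rigid copy of some query triplets
# (guaranteed structure) plus distractors
random_cluster_instance <- function(m = 8, n = 5, planted = 3, noise = 0.05) {
  qtrips <- replicate(m, random_triplet(), simplify = FALSE)
  R <- random_rotation_matrix(); tv <- runif(3, -10, 10)
  src <- sample(m, min(planted, m))
  ttrips <- lapply(src, function(i) {
    rigidly_move(qtrips[[i]], R, tv) + matrix(rnorm(9, 0, noise), 3, 3)
  })
  while (length(ttrips) < n) {
    ttrips[[length(ttrips) + 1L]] <- random_triplet()
  }
  list(q = qtrips, t = ttrips)
}

toy_cache <- new.env(parent = emptyenv())

cached_toy <- function(n, seed, noise_range = NULL) {
  key <- paste0("toy_", n, "_", seed, "_", paste(noise_range, collapse = "_"))
  if (is.null(toy_cache[[key]])) {
    params <- list()
    if (!is.null(noise_range)) params$noise_range <- noise_range
    toy_cache[[key]] <- make_toy_dataset(n, params = params, seed = seed)
  }
  toy_cache[[key]]
}
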