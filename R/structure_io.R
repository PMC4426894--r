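#' @title Protein structure input
#' @name structure_io
#' @description
#' Readers for PDB-format coordinates and DSSP secondary-structure files,
#' producing per-chain residue lists with backbone N-CA-C triplets and the
#' bound NAD/FAD heteroatom groups that seed template construction.
NULL

SUPPORTED_LIGANDS <- c("NAD", "FAD")

# Residue names treated as protein (standard + mapped nonstandard).
protein_res_names <- function() c(names(AA3TO1), names(NONSTANDARD_MAP))

new_triplet <- function(n, ca, c) {
  m <- rbind(N = as.numeric(n), CA = as.numeric(ca), C = as.numeric(c))
  colnames(m) <- c("x", "y", "z")
  m
}

triplet_geometry_ok <- function(trip) {
  d1 <- vec_norm(trip["N", ] - trip["CA", ])
  d2 <- vec_norm(trip["CA", ] - trip["C", ])
  d1 > 1.0 && d1 < 2.5 && d2 > 1.0 && d2 < 2.5
}

#' Parse protein chains and NAD/FAD ligands from PDB text
#'
#' Reads ATOM/HETATM records of the first model, resolves alternate
#' locations (highest occupancy wins; ties broken by alphabetical alt-loc
#' identifier) and returns a structure model: one residue unit per
#' (chain, residue number + insertion code), each with a backbone triplet
#' when all of N, CA, C are present with sane bond geometry, plus one
#' ligand instance per NAD/FAD heteroatom group.  Nonstandard residues
#' with a known parent (e.g. MSE) are kept as protein; other heteroatoms
#' except NAD/FAD are dropped.
#'
#' @param pdb_text character scalar or vector of PDB lines.
#' @param model_policy only `"first_model"` is supported.
#' @param pdb_id identifier stored in the model; defaults to the HEADER id
#'   or `"UNKN"`.
#' @return a `structure_model`: list with `pdb_id`, `chains` (named list of
#'   residue-unit lists) and `ligands`.
#' @export
parse_pdb_chains <- function(pdb_text, model_policy = c("first_model"),
                             pdb_id = NULL) {
  model_policy <- match.arg(model_policy)
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  if (is.null(pdb_id)) {
    hdr <- lines[rec == "HEADER"]
    pdb_id <- if (length(hdr)) trimws(substr(hdr[1], 63, 66)) else ""
    if (!nzchar(pdb_id)) pdb_id <- "UNKN"
  }
  # first-model policy
  mstart <- which(rec == "MODEL ")
  if (length(mstart)) {
    mend <- which(rec == "ENDMDL")
    stop_at <- if (length(mend)) mend[1] else length(lines)
    keep <- seq_along(lines) > mstart[1] & seq_along(lines) < stop_at
    keep <- keep | !(rec %in% c("ATOM  ", "HETATM", "ANISOU"))
    lines <- lines[keep]
    rec <- substr(lines, 1, 6)
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(substr(lines, 1, 4) == "ATOM")) {
    stop("parse error: no ATOM record in input")
  }
  al <- lines[is_atom]
  df <- data.frame(
    record   = trimws(substr(al, 1, 6)),
    name     = trimws(substr(al, 13, 16)),
    alt_loc  = substr(al, 17, 17),
    res_name = trimws(substr(al, 18, 20)),
    chain_id = substr(al, 22, 22),
    seq_pos  = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode    = trimws(substr(al, 27, 27)),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element  = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1.0
  df <- df[!is.na(df$x) & !is.na(df$y) & !is.na(df$z), , drop = FALSE]
  if (!all(is.finite(c(df$x, df$y, df$z)))) stop("parse error: non-finite coordinates")
  df$element[!nzchar(df$element)] <- substr(df$name[!nzchar(df$element)], 1, 1)
  df$seq_key <- paste0(df$seq_pos, df$icode)
  df$file_order <- seq_len(nrow(df))

  # alt-loc resolution per (chain, residue, atom name)
  akey <- paste(df$chain_id, df$seq_key, df$res_name, df$name, sep = "\r")
  if (anyDuplicated(akey)) {
    ord <- order(akey, -df$occupancy, df$alt_loc, df$file_order)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain_id, df$seq_key, df$res_name, df$name,
                               sep = "\r")), , drop = FALSE]
    df <- df[order(df$file_order), , drop = FALSE]
  }

  is_lig <- df$record == "HETATM" & df$res_name %in% SUPPORTED_LIGANDS
  is_prot <- df$res_name %in% protein_res_names() & !is_lig

  ligands <- list()
  if (any(is_lig)) {
    ld <- df[is_lig, , drop = FALSE]
    for (key in unique(paste(ld$res_name, ld$chain_id, ld$seq_key, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- ld[paste(ld$res_name, ld$chain_id, ld$seq_key, sep = "\r") == key, ]
      ligands[[length(ligands) + 1L]] <- list(
        ligand_code = parts[1], chain_id = parts[2],
        het_seq = suppressWarnings(as.integer(parts[3])),
        atoms = sub[, c("name", "element", "x", "y", "z")]
      )
    }
  }

  chains <- list()
  if (any(is_prot)) {
    pd <- df[is_prot, , drop = FALSE]
    rkey <- paste(pd$chain_id, pd$seq_key, sep = "\r")
    for (key in unique(rkey)) {
      sub <- pd[rkey == key, , drop = FALSE]
      cid <- sub$chain_id[1]
      trip <- NULL
      bb <- c("N", "CA", "C")
      if (all(bb %in% sub$name)) {
        g <- function(nm) unlist(sub[match(nm, sub$name), c("x", "y", "z")])
        cand <- new_triplet(g("N"), g("CA"), g("C"))
        if (triplet_geometry_ok(cand)) {
          trip <- cand
        } else {
          warning(sprintf("residue %s %s%s: backbone bond lengths out of range; triplet dropped",
                          cid, sub$seq_pos[1], sub$icode[1]), call. = FALSE)
        }
      } else {
        warning(sprintf("residue %s %s%s missing backbone atom(s); no triplet",
                        cid, sub$seq_pos[1], sub$icode[1]), call. = FALSE)
      }
      ru <- list(
        chain_id = cid,
        seq_pos = sub$seq_pos[1],
        icode = sub$icode[1],
        seq_key = sub$seq_key[1],
        res_name = sub$res_name[1],
        one_letter = residue_one_letter(sub$res_name[1]),
        atoms = sub[, c("name", "element", "x", "y", "z")],
        triplet = trip,
        ss = "-"
      )
      if (is.null(chains[[cid]])) chains[[cid]] <- list()
      chains[[cid]][[length(chains[[cid]]) + 1L]] <- ru
    }
  }
  structure(list(pdb_id = pdb_id, chains = chains, ligands = ligands),
            class = "structure_model")
}

#' Extract backbone triplets from a chain
#'
#' Returns the N-CA-C triplets of residues that have one, preserving the
#' chain order.  The `positions` attribute records each triplet's residue
#' index within the chain and the names carry the residue sequence keys.
#'
#' @param chain list of residue units (one chain of a `structure_model`).
#' @return named list of 3x3 triplet matrices with attribute `positions`.
#' @export
extract_triplets <- function(chain) {
  if (!length(chain)) stop("empty chain")
  has <- vapply(chain, function(r) !is.null(r$triplet), logical(1))
  if (!any(has)) stop("no residue in the chain has a complete backbone triplet")
  trips <- lapply(chain[has], `[[`, "triplet")
  names(trips) <- vapply(chain[has], `[[`, character(1), "seq_key")
  attr(trips, "positions") <- which(has)
  trips
}

# flatten a list of triplets to a k x 9 matrix (N, CA, C xyz)
triplets_to_matrix <- function(trips) {
  t(vapply(trips, function(m) as.numeric(t(m)), numeric(9)))
}

#' Read a classic DSSP flat file
#'
#' @param dssp_text character scalar or vector of DSSP output lines.
#' @return data.frame with `chain_id`, `seq_key`, `ss_label` (8-state;
#'   blank and unknown characters map to `"-"`).
#' @export
read_dssp <- function(dssp_text) {
  lines <- if (length(dssp_text) == 1L) strsplit(dssp_text, "\n", fixed = TRUE)[[1]] else dssp_text
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("DSSP format error: missing '  #  RESIDUE' header")
  body <- lines[seq.int(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"] # chain breaks
  if (!length(body)) {
    return(data.frame(chain_id = character(), seq_key = character(),
                      ss_label = character(), stringsAsFactors = FALSE))
  }
  num <- trimws(substr(body, 6, 10))
  icode <- trimws(substr(body, 11, 11))
  chain <- substr(body, 12, 12)
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  bad <- !(ss %in% c("H", "G", "I", "E", "B", "T", "S", "-"))
  if (any(bad)) {
    warning(sprintf("%d unknown secondary-structure character(s) mapped to '-'",
                    sum(bad)), call. = FALSE)
    ss[bad] <- "-"
  }
  data.frame(chain_id = chain, seq_key = paste0(num, icode),
             ss_label = ss, stringsAsFactors = FALSE)
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

in_window <- function(x, lo, hi) !is.na(x) & x > lo & x < hi

# Dihedral-window fallback secondary-structure rule for one chain:
# H when phi in (-77,-37) and psi in (-67,-27) for >=3 consecutive residues,
# E when phi in (-149,-89) and psi in (83,143) for >=2 consecutive residues.
fallback_ss_chain <- function(chain) {
  n <- length(chain)
  ss <- rep("-", n)
  if (n < 2) return(ss)
  trips <- lapply(chain, `[[`, "triplet")
  phi <- psi <- rep(NA_real_, n)
  bonded <- function(i) {
    # peptide bond continuity between residue i and i+1
    if (is.null(trips[[i]]) || is.null(trips[[i + 1]])) return(FALSE)
    vec_norm(trips[[i]]["C", ] - trips[[i + 1]]["N", ]) < 2.5
  }
  for (i in seq_len(n)) {
    if (is.null(trips[[i]])) next
    if (i > 1 && bonded(i - 1)) {
      phi[i] <- dihedral_deg(trips[[i - 1]]["C", ], trips[[i]]["N", ],
                             trips[[i]]["CA", ], trips[[i]]["C", ])
    }
    if (i < n && bonded(i)) {
      psi[i] <- dihedral_deg(trips[[i]]["N", ], trips[[i]]["CA", ],
                             trips[[i]]["C", ], trips[[i + 1]]["N", ])
    }
  }
  hcand <- in_window(phi, -77, -37) & in_window(psi, -67, -27)
  ecand <- in_window(phi, -149, -89) & in_window(psi, 83, 143)
  mark_runs <- function(cand, min_run, label) {
    r <- rle(cand)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_run) {
        ss[pos:(pos + r$lengths[k] - 1L)] <<- label
      }
      pos <- pos + r$lengths[k]
    }
  }
  mark_runs(hcand, 3L, "H")
  mark_runs(ecand, 2L, "E")
  ss
}

#' Assign secondary-structure labels to a model
#'
#' When DSSP text is supplied its 8-state labels are used verbatim; every
#' DSSP residue must exist in the model (by chain and residue number).
#' Without DSSP, a deterministic dihedral-window fallback assigns H/E/-
#' (helix and strand phi/psi windows over consecutive residues).  Every
#' residue receives a label, defaulting to `"-"`.
#'
#' @param model a `structure_model`.
#' @param dssp_text optional DSSP file text.
#' @return named character vector of labels keyed `"<chain>:<seq_key>"`.
#' @export
assign_secondary_structure <- function(model, dssp_text = NULL) {
  labels <- character(0)
  for (cid in names(model$chains)) {
    chain <- model$chains[[cid]]
    keys <- paste0(cid, ":", vapply(chain, `[[`, character(1), "seq_key"))
    labels[keys] <- "-"
  }
  if (is.null(dssp_text)) {
    for (cid in names(model$chains)) {
      chain <- model$chains[[cid]]
      keys <- paste0(cid, ":", vapply(chain, `[[`, character(1), "seq_key"))
      labels[keys] <- fallback_ss_chain(chain)
    }
  } else {
    tab <- read_dssp(dssp_text)
    keys <- paste0(tab$chain_id, ":", tab$seq_key)
    missing <- setdiff(keys, names(labels))
    if (length(missing)) {
      stop("DSSP/model alignment error: DSSP residues absent from model: ",
           paste(missing, collapse = ", "))
    }
    labels[keys] <- tab$ss_label
  }
  labels
}

#' Write secondary-structure labels into a model
#'
#' @param model a `structure_model`.
#' @param labels named vector from [assign_secondary_structure()].
#' @return the model with each residue's `ss` field set.
#' @export
apply_ss_labels <- function(model, labels) {
  for (cid in names(model$chains)) {
    for (k in seq_along(model$chains[[cid]])) {
      key <- paste0(cid, ":", model$chains[[cid]][[k]]$seq_key)
      if (key %in% names(labels)) model$chains[[cid]][[k]]$ss <- unname(labels[key])
    }
  }
  model
}
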