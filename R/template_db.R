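#' @title Binding-residue template construction
#' @name template_db
#' @description
#' Decomposes bound NAD/FAD ligands into their three chemical moieties
#' (nicotinamide or flavin, adenosine, phosphate), identifies the residues
#' contacting each moiety, assembles binding templates of two or more
#' residues and serializes the template database as JSON lines.
NULL

TEMPLATE_DB_VERSION <- 1L

moiety_names <- function(ligand_code) {
  switch(toupper(ligand_code),
         NAD = c("nicotinamide", "adenosine", "phosphate"),
         FAD = c("flavin", "adenosine", "phosphate"),
         stop("unsupported ligand code: ", ligand_code))
}

#' Moiety atom-name partition for a cofactor
#'
#' Returns the built-in partition of PDB Chemical Component Dictionary
#' atom names into the three moieties of NAD or FAD.  The tables live in
#' `inst/extdata/moieties_<code>.tsv` and can be overridden with a custom
#' file of the same layout (columns `atom_name`, `moiety`).
#'
#' @param ligand_code `"NAD"` or `"FAD"`.
#' @param path optional custom table path.
#' @return named list: moiety -> character vector of atom names.
#' @export
moiety_partition <- function(ligand_code, path = NULL) {
  ligand_code <- toupper(ligand_code)
  moieties <- moiety_names(ligand_code) # validates the code
  if (is.null(path)) {
    path <- system.file("extdata", paste0("moieties_", ligand_code, ".tsv"),
                        package = "fragsite")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("no moiety partition table for ligand ", ligand_code)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  split(tab$atom_name, tab$moiety)[moieties]
}

#' Partition a ligand instance into its three moieties
#'
#' Assigns every heavy atom of a bound NAD/FAD to one moiety using the
#' atom-name partition and computes each moiety's unweighted geometric
#' center \eqn{L_\omega}.  Atoms with unrecognized names are attached to
#' the nearest moiety center with a warning; hydrogens are ignored.
#'
#' @param ligand a ligand instance from [parse_pdb_chains()].
#' @param partition optional partition list from [moiety_partition()].
#' @return list of moieties, each `list(moiety, atom_names, center, atoms)`.
#' @export
partition_ligand_moieties <- function(ligand, partition = NULL) {
  code <- toupper(ligand$ligand_code)
  if (!code %in% SUPPORTED_LIGANDS) stop("unsupported ligand code: ", code)
  if (is.null(partition)) partition <- moiety_partition(code)
  atoms <- ligand$atoms
  if (!nrow(atoms)) stop("ligand has no atoms")
  atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  assign <- rep(NA_character_, nrow(atoms))
  for (m in names(partition)) assign[atoms$name %in% partition[[m]]] <- m
  if (all(is.na(assign))) {
    stop("moiety partition error: no atom name of ligand ", code,
         " matched the partition table")
  }
  centers <- lapply(names(partition), function(m) {
    sub <- atoms[which(assign == m), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    colMeans(as.matrix(sub[, c("x", "y", "z")]))
  })
  names(centers) <- names(partition)
  if (any(is.na(assign))) {
    warning(sprintf("%d unrecognized ligand atom name(s) assigned by nearest moiety center",
                    sum(is.na(assign))), call. = FALSE)
    have <- names(partition)[!vapply(centers, is.null, logical(1))]
    for (k in which(is.na(assign))) {
      p <- as.numeric(atoms[k, c("x", "y", "z")])
      d <- vapply(have, function(m) vec_norm(p - centers[[m]]), numeric(1))
      assign[k] <- have[which.min(d)]
    }
  }
  out <- list()
  for (m in names(partition)) {
    idx <- which(assign == m)
    if (!length(idx)) {
      warning("moiety ", m, " has no atoms in this ligand instance", call. = FALSE)
      next
    }
    sub <- atoms[idx, , drop = FALSE]
    out[[m]] <- list(
      moiety = m,
      atom_names = sub$name,
      center = colMeans(as.matrix(sub[, c("x", "y", "z")])),
      atoms = sub
    )
  }
  out
}

residue_min_dist <- function(residue, coords) {
  ra <- as.matrix(residue$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(ra^2), rowSums(coords^2), "+") - 2 * (ra %*% t(coords))
  sqrt(max(0, min(d2)))
}

#' Residues contacting one ligand moiety
#'
#' Purely geometric rule: a residue binds moiety \eqn{\omega} when any of
#' its atoms lies within `cutoff` of any \eqn{\omega} atom.  When a
#' binding annotation is supplied the geometric set is intersected with
#' the annotated binding positions.  A residue may qualify for several
#' moieties.
#'
#' @param chain list of residue units.
#' @param moiety one moiety from [partition_ligand_moieties()].
#' @param annotation optional binding annotation
#'   (`list(pdb_id, chain_id, ligand_code, binding_positions)`).
#' @param cutoff contact distance in Angstrom (default 3.5).
#' @return character vector of residue sequence keys.
#' @export
identify_binding_residues <- function(chain, moiety, annotation = NULL,
                                      cutoff = 3.5) {
  if (!length(chain)) stop("empty chain")
  stopifnot(cutoff > 0)
  mc <- as.matrix(moiety$atoms[, c("x", "y", "z")])
  hit <- vapply(chain, function(r) residue_min_dist(r, mc) <= cutoff, logical(1))
  keys <- vapply(chain, `[[`, character(1), "seq_key")[hit]
  if (!is.null(annotation)) {
    keys <- intersect(keys, as.character(annotation$binding_positions))
  }
  keys
}

#' Build binding templates from one ligand-bound structure
#'
#' For every (chain, ligand instance, moiety) triple the contacting
#' residues form one binding template provided at least two of them carry
#' a backbone triplet; smaller groups are discarded.  The template stores
#' the residues' identities, triplets and secondary-structure labels
#' together with the moiety's geometric center.
#'
#' @param model a `structure_model` (run [apply_ss_labels()] first if
#'   secondary-structure labels should be carried into the templates).
#' @param annotation optional binding annotation or list of annotations
#'   matched by chain and ligand code.
#' @param params list; honoured entries `cutoff` (default 3.5 Angstrom)
#'   and `ligand_kind` (default: code of the first supported ligand).
#' @return a `template_database`.
#' @export
build_templates <- function(model, annotation = NULL, params = list()) {
  cutoff <- params$cutoff %||% 3.5
  ligs <- Filter(function(l) toupper(l$ligand_code) %in% SUPPORTED_LIGANDS,
                 model$ligands)
  if (!length(ligs)) stop("no supported ligand (NAD/FAD) in model ", model$pdb_id)
  ligand_kind <- toupper(params$ligand_kind %||% ligs[[1]]$ligand_code)
  ligs <- Filter(function(l) toupper(l$ligand_code) == ligand_kind, ligs)
  if (!length(ligs)) stop("no ", ligand_kind, " ligand in model ", model$pdb_id)
  if (!is.null(annotation) && !is.null(annotation$binding_positions)) {
    annotation <- list(annotation)
  }
  templates <- list()
  for (lig in ligs) {
    moieties <- partition_ligand_moieties(lig)
    for (cid in names(model$chains)) {
      chain <- model$chains[[cid]]
      ann <- NULL
      if (!is.null(annotation)) {
        for (a in annotation) {
          if (identical(a$chain_id, cid) &&
              identical(toupper(a$ligand_code), ligand_kind) &&
              (is.null(a$pdb_id) || !nzchar(model$pdb_id) ||
               identical(tolower(a$pdb_id), tolower(model$pdb_id)))) {
            ann <- a
            break
          }
        }
        if (is.null(ann)) next # annotated build: chains without a row skipped
      }
      for (m in names(moieties)) {
        keys <- identify_binding_residues(chain, moieties[[m]], ann, cutoff)
        sel <- chain[vapply(chain, function(r) r$seq_key %in% keys, logical(1))]
        sel <- Filter(function(r) !is.null(r$triplet), sel)
        if (length(sel) < 2) next
        templates[[length(templates) + 1L]] <- list(
          template_id = sprintf("%s_%s_%s%s_%s", model$pdb_id, cid,
                                lig$ligand_code, lig$het_seq, m),
          pdb_id = model$pdb_id,
          chain_id = cid,
          het_seq = lig$het_seq,
          moiety = m,
          ligand_center = as.numeric(moieties[[m]]$center),
          residues = lapply(sel, function(r) {
            list(seq_key = r$seq_key, res_name = r$res_name,
                 one_letter = r$one_letter, ss = r$ss, triplet = r$triplet)
          })
        )
      }
    }
  }
  if (!length(templates)) {
    warning("no binding template survived the >=2 residue rule", call. = FALSE)
  }
  structure(list(ligand_kind = ligand_kind, templates = templates,
                 provenance = list(cutoff = cutoff,
                                   annotation_source = if (is.null(annotation)) "geometric" else "annotation",
                                   version = TEMPLATE_DB_VERSION)),
            class = "template_database")
}

#' Build a template database from several structures
#'
#' Convenience wrapper around [build_templates()] that concatenates the
#' templates of every model; models that yield none are skipped with a
#' warning.
#'
#' @param models list of `structure_model`s.
#' @param annotations optional list of binding annotations.
#' @param params passed to [build_templates()].
#' @return a `template_database`.
#' @export
build_template_db <- function(models, annotations = NULL, params = list()) {
  dbs <- list()
  for (model in models) {
    db <- tryCatch(build_templates(model, annotations, params),
                   error = function(e) {
                     warning("model ", model$pdb_id, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (!is.null(db) && length(db$templates)) dbs[[length(dbs) + 1L]] <- db
  }
  if (!length(dbs)) stop("no templates built from any model")
  out <- dbs[[1]]
  for (k in seq_along(dbs)[-1]) out$templates <- c(out$templates, dbs[[k]]$templates)
  ids <- vapply(out$templates, `[[`, character(1), "template_id")
  if (anyDuplicated(ids)) stop("duplicate template ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Serialize a template database as JSON lines
#'
#' One header line (format tag, version, ligand kind, provenance) followed
#' by one JSON object per template; coordinates keep full precision so
#' that [read_template_db()] round-trips exactly.
#'
#' @param db a `template_database`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_template_db <- function(db, path) {
  stopifnot(inherits(db, "template_database"))
  hdr <- jsonlite::toJSON(list(format = "fragsite_template_db",
                               version = TEMPLATE_DB_VERSION,
                               ligand_kind = db$ligand_kind,
                               provenance = db$provenance),
                          auto_unbox = TRUE, digits = NA)
  lines <- vapply(db$templates, function(tpl) {
    tpl$residues <- lapply(tpl$residues, function(r) {
      r$triplet <- as.numeric(t(r$triplet)) # row-major N,CA,C
      r
    })
    tpl$n_residues <- length(tpl$residues)
    as.character(jsonlite::toJSON(tpl, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' Read a template database written by [write_template_db()]
#'
#' @param path JSON-lines file.
#' @return a `template_database`.
#' @export
read_template_db <- function(path) {
  if (!file.exists(path)) stop("template DB file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("template DB format error: empty file")
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) stop("template DB format error: bad header"))
  if (!identical(hdr$format, "fragsite_template_db")) {
    stop("template DB format error: missing format tag")
  }
  if (!identical(as.integer(hdr$version), TEMPLATE_DB_VERSION)) {
    stop("template DB version mismatch: file has ", hdr$version,
         ", expected ", TEMPLATE_DB_VERSION)
  }
  templates <- lapply(lines[-1], function(ln) {
    tpl <- tryCatch(jsonlite::fromJSON(ln, simplifyDataFrame = FALSE),
                    error = function(e) stop("template DB format error: unparseable line"))
    if (length(tpl$residues) != tpl$n_residues) {
      stop("template DB format error: corrupted residue count in template ",
           tpl$template_id)
    }
    tpl$residues <- lapply(tpl$residues, function(r) {
      if (length(r$triplet) != 9) {
        stop("template DB format error: bad triplet in template ", tpl$template_id)
      }
      r$triplet <- new_triplet(r$triplet[1:3], r$triplet[4:6], r$triplet[7:9])
      r
    })
    tpl$ligand_center <- as.numeric(tpl$ligand_center)
    tpl$n_residues <- NULL
    tpl
  })
  structure(list(ligand_kind = hdr$ligand_kind, templates = templates,
                 provenance = hdr$provenance),
            class = "template_database")
}

#' Parse a BioLiP-style binding-annotation table
#'
#' Whitespace-delimited rows: PDB id, chain, ligand code, then residue
#' tokens such as `"G37 K40"` (an optional one-letter residue prefix
#' followed by the residue number, possibly with an insertion code).
#' Rows with an unparseable token are skipped with a warning; duplicate
#' rows are removed.
#'
#' @param text character scalar or vector of table lines.
#' @return list of annotations
#'   `list(pdb_id, chain_id, ligand_code, binding_positions)`.
#' @export
read_biolip_annotations <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  seen <- character(0)
  for (ln in lines) {
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) < 3) {
      warning("annotation row skipped (too few fields): ", ln, call. = FALSE)
      next
    }
    restok <- tok[-(1:3)]
    m <- regmatches(restok, regexec("^[A-Za-z]?(-?[0-9]+[A-Za-z]?)$", restok))
    pos <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
                  character(1))
    if (anyNA(pos)) {
      warning("annotation row skipped (unparseable residue token): ", ln,
              call. = FALSE)
      next
    }
    if (!length(pos)) {
      warning("annotation row with empty binding-position list: ", ln,
              call. = FALSE)
    }
    key <- paste(tok[1], tok[2], toupper(tok[3]),
                 paste(sort(unique(pos)), collapse = ","), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(pdb_id = tok[1], chain_id = tok[2],
                                    ligand_code = toupper(tok[3]),
                                    binding_positions = unique(pos))
  }
  out
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Composition statistics of binding sites
#'
#' Compares, per moiety, the amino-acid frequency among template residues
#' with the whole-protein frequency over all supplied models (ratio
#' column = binding / whole), and counts protein atoms within `cutoff` of
#' each moiety's atoms split into backbone (N, CA, C, O) and side-chain
#' contacts by element.
#'
#' @param db a `template_database`.
#' @param models list of `structure_model`s consistent with `db`.
#' @param cutoff contact distance in Angstrom (default 3.5).
#' @return list with data.frames `residue_stats` and `atom_stats`.
#' @export
binding_composition_stats <- function(db, models, cutoff = 3.5) {
  if (!length(db$templates)) stop("empty template database")
  # whole-protein residue frequencies
  all_res <- unlist(lapply(models, function(m) {
    unlist(lapply(m$chains, function(ch) vapply(ch, `[[`, character(1), "res_name")))
  }))
  whole_tab <- table(all_res) / length(all_res)
  rows <- list()
  for (m in unique(vapply(db$templates, `[[`, character(1), "moiety"))) {
    tps <- Filter(function(t) t$moiety == m, db$templates)
    bres <- unlist(lapply(tps, function(t) vapply(t$residues, `[[`, character(1), "res_name")))
    btab <- table(bres) / length(bres)
    for (rn in names(btab)) {
      wf <- if (rn %in% names(whole_tab)) as.numeric(whole_tab[rn]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        moiety = m, res_name = rn,
        binding_freq = as.numeric(btab[rn]), whole_freq = wf,
        ratio = if (wf > 0) as.numeric(btab[rn]) / wf else Inf,
        stringsAsFactors = FALSE)
    }
  }
  residue_stats <- do.call(rbind, rows)
  # atom contacts
  arow <- list()
  for (model in models) {
    ligs <- Filter(function(l) toupper(l$ligand_code) == db$ligand_kind,
                   model$ligands)
    if (!length(ligs)) next
    prot <- do.call(rbind, unlist(lapply(model$chains, function(ch) {
      lapply(ch, function(r) r$atoms)
    }), recursive = FALSE))
    pm <- as.matrix(prot[, c("x", "y", "z")])
    for (lig in ligs) {
      for (mo in partition_ligand_moieties(lig)) {
        lm <- as.matrix(mo$atoms[, c("x", "y", "z")])
        d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * (pm %*% t(lm))
        close_idx <- which(sqrt(pmax(d2, 0)) <= cutoff, arr.ind = TRUE)[, 1]
        if (!length(close_idx)) next
        sub <- prot[unique(close_idx), , drop = FALSE]
        arow[[length(arow) + 1L]] <- data.frame(
          moiety = mo$moiety,
          element = toupper(sub$element),
          backbone = sub$name %in% BACKBONE_ATOMS,
          stringsAsFactors = FALSE)
      }
    }
  }
  atom_stats <- if (length(arow)) {
    ad <- do.call(rbind, arow)
    agg <- aggregate(list(count = rep(1L, nrow(ad))),
                     by = list(moiety = ad$moiety, element = ad$element,
                               backbone = ad$backbone), FUN = sum)
    agg[order(agg$moiety, agg$element, agg$backbone), , drop = FALSE]
  } else {
    data.frame(moiety = character(), element = character(),
               backbone = logical(), count = integer())
  }
  list(residue_stats = residue_stats, atom_stats = atom_stats)
}
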