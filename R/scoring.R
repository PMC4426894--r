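#' @title Composite binding score
#' @name scoring
#' @description
#' Turns cluster alignments into per-residue binding scores: the product
#' of alignment size, a C-alpha RMSD term, BLOSUM62 sequence similarity
#' and secondary-structure similarity; back-projection of the template's
#' ligand center into query coordinates; a cross-moiety proximity boost;
#' and per-protein z-normalization.
NULL

#' Load a plain-text substitution matrix
#'
#' Square whitespace-delimited matrix with a header row and a leading
#' symbol column, as in the shipped `BLOSUM62.txt`.
#'
#' @param path matrix file.
#' @return numeric matrix with symbol dimnames.
#' @export
load_substitution_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           row.names = 1, comment.char = "#")
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    stop("substitution matrix is not square or has mismatched labels")
  }
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix is not symmetric")
  m
}

.matrix_cache <- new.env(parent = emptyenv())

#' The shipped BLOSUM62 matrix
#' @return numeric matrix (24 x 24, NCBI layout).
#' @export
blosum62_matrix <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    .matrix_cache$blosum62 <- load_substitution_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "fragsite"))
  }
  .matrix_cache$blosum62
}

#' The default secondary-structure substitution matrix
#'
#' A 3-state matrix over H/E/- (match +2, mismatch -1).  Eight-state DSSP
#' labels are collapsed before lookup (H,G,I -> H; E,B -> E; rest -> -).
#' Replaceable via [load_substitution_matrix()].
#' @return numeric matrix.
#' @export
ss_default_matrix <- function() {
  if (is.null(.matrix_cache$ss3)) {
    .matrix_cache$ss3 <- load_substitution_matrix(
      system.file("extdata", "ss3_matrix.txt", package = "fragsite"))
  }
  .matrix_cache$ss3
}

#' Collapse 8-state DSSP labels to 3 states
#' @param ss character vector of 8-state labels.
#' @return character vector over H, E, -.
#' @export
collapse_ss3 <- function(ss) {
  out <- rep("-", length(ss))
  out[ss %in% c("H", "G", "I")] <- "H"
  out[ss %in% c("E", "B")] <- "E"
  out
}

#' RMSD score component
#'
#' `1 / (1 + rmsd)` for clusters passing the hard RMSD filter; clusters at
#' or above `rmsd_max` are rejected (sentinel `NA`, not a zero score).
#'
#' @param rmsd C-alpha RMSD in Angstrom (non-negative).
#' @param rmsd_max rejection bound, default 3.0 Angstrom.
#' @return score in (1/(1+rmsd_max), 1], or `NA_real_` for a rejected
#'   cluster.
#' @export
rmsd_component <- function(rmsd, rmsd_max = 3.0) {
  if (any(rmsd < 0)) stop("negative RMSD")
  ifelse(rmsd < rmsd_max, 1 / (1 + rmsd), NA_real_)
}

substitution_component <- function(q, t, matrix, what) {
  stopifnot(length(q) == length(t), length(q) > 0)
  unknown <- unique(c(q, t)[!(c(q, t) %in% rownames(matrix))])
  if (length(unknown)) {
    stop("unknown ", what, " symbol(s): ", paste(unknown, collapse = ", "))
  }
  raw <- sum(matrix[cbind(q, t)])
  self <- sum(matrix[cbind(t, t)])
  list(raw = raw, score = raw / (self + 1))
}

#' BLOSUM sequence-similarity component
#'
#' Raw score = sum of substitution scores over the aligned residue pairs;
#' normalized as raw / (template self-score + 1).
#'
#' @param aligned_pairs 2-column matrix or data.frame of one-letter codes
#'   (query, template).
#' @param matrix substitution matrix, default [blosum62_matrix()].
#' @return `list(raw, score)`.
#' @export
blosum_component <- function(aligned_pairs, matrix = blosum62_matrix()) {
  ap <- as.matrix(aligned_pairs)
  substitution_component(ap[, 1], ap[, 2], matrix, "residue")
}

#' Secondary-structure similarity component
#'
#' Same normalization as [blosum_component()], over secondary-structure
#' labels.  With the default 3-state matrix, 8-state labels are collapsed
#' first.
#'
#' @param aligned_pairs 2-column matrix or data.frame of labels
#'   (query, template).
#' @param matrix substitution matrix, default [ss_default_matrix()].
#' @return `list(raw, score)`.
#' @export
dssp_component <- function(aligned_pairs, matrix = ss_default_matrix()) {
  ap <- as.matrix(aligned_pairs)
  q <- ap[, 1]; t <- ap[, 2]
  if (identical(dim(matrix), c(3L, 3L)) ||
      all(rownames(matrix) %in% c("H", "E", "-"))) {
    q <- collapse_ss3(q); t <- collapse_ss3(t)
  }
  substitution_component(q, t, matrix, "secondary-structure")
}

#' Default scoring parameters
#'
#' @return list of the tunable constants: `d0` (2.0), `min_size` (2),
#'   `resid_max` (0.5), `rmsd_max` (3.0), `binding_cutoff` (3.5),
#'   `boost_range` (c(3, 9)), `boost_mode` ("sum"), `fpr_cap` (0.05),
#'   `z_threshold` (1.645), `seed` (42).
#' @export
default_params <- function() {
  list(d0 = 2.0, min_size = 2L, resid_max = 0.5, rmsd_max = 3.0,
       binding_cutoff = 3.5, boost_range = c(3, 9), boost_mode = "sum",
       fpr_cap = 0.05, z_threshold = 1.645, seed = 42L)
}

merge_params <- function(params) {
  p <- default_params()
  for (nm in names(params)) p[[nm]] <- params[[nm]]
  p
}

#' Per-residue binding scores for one query chain
#'
#' Aligns the query against every template of the database (optionally
#' excluding templates from a given source PDB entry, the leave-one-out
#' rule), keeps clusters passing the C-alpha RMSD filter, and assigns each
#' residue the maximum composite score
#' size x RMSD-term x BLOSUM-term x SS-term over the clusters containing
#' it.  The winning cluster also yields the residue's moiety label and a
#' predicted ligand center: the template's moiety center carried through
#' the inverse representative transform.
#'
#' @param chain list of residue units (with `ss` labels set).
#' @param db a `template_database`.
#' @param params list overriding [default_params()]; `exclude_pdb` names
#'   source PDB id(s) whose templates are skipped.
#' @return data.frame with one row per chain residue: `chain_id`,
#'   `seq_key`, `seq_pos`, `res_name`, `score`, `moiety`, `theta_x/y/z`,
#'   `template_id`, `epsilon`, `rmsd_ca`.
#' @export
residue_binding_scores <- function(chain, db, params = list()) {
  p <- merge_params(params)
  stopifnot(length(db$templates) >= 0)
  usable <- vapply(chain, function(r) {
    !is.null(r$triplet) && !is.na(r$one_letter)
  }, logical(1))
  n <- length(chain)
  out <- data.frame(
    chain_id = vapply(chain, `[[`, character(1), "chain_id"),
    seq_key = vapply(chain, `[[`, character(1), "seq_key"),
    seq_pos = vapply(chain, `[[`, numeric(1), "seq_pos"),
    res_name = vapply(chain, `[[`, character(1), "res_name"),
    score = 0, moiety = NA_character_,
    theta_x = NA_real_, theta_y = NA_real_, theta_z = NA_real_,
    template_id = NA_character_, epsilon = NA_integer_, rmsd_ca = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!any(usable)) return(out)
  sub <- chain[usable]
  idx_map <- which(usable)
  qtrips <- lapply(sub, `[[`, "triplet")
  qaa <- vapply(sub, `[[`, character(1), "one_letter")
  qss <- vapply(sub, `[[`, character(1), "ss")
  blosum <- p$blosum %||% blosum62_matrix()
  ssmat <- p$ssmat %||% ss_default_matrix()
  exclude <- tolower(p$exclude_pdb %||% character(0))
  best <- rep(-Inf, n)
  for (tpl in db$templates) {
    if (tolower(tpl$pdb_id) %in% exclude) next
    taa <- vapply(tpl$residues, `[[`, character(1), "one_letter")
    tss <- vapply(tpl$residues, `[[`, character(1), "ss")
    ttrips <- lapply(tpl$residues, `[[`, "triplet")
    clusters <- cluster_triplet_pairs(qtrips, ttrips, d0 = p$d0,
                                      min_size = p$min_size,
                                      resid_max = p$resid_max)
    for (cl in clusters) {
      cr <- rmsd_component(cl$rmsd_ca, p$rmsd_max)
      if (is.na(cr)) next
      cb <- blosum_component(cbind(qaa[cl$s_mu], taa[cl$t_mu]), blosum)$score
      cd <- dssp_component(cbind(qss[cl$s_mu], tss[cl$t_mu]), ssmat)$score
      sc <- cl$epsilon * cr * cb * cd
      theta <- apply_transform(invert_transform(cl$rep_transform),
                               tpl$ligand_center)
      for (k in seq_along(cl$s_mu)) {
        i <- idx_map[cl$s_mu[k]]
        if (sc > best[i]) {
          best[i] <- sc
          out$score[i] <- sc
          out$moiety[i] <- tpl$moiety
          out$template_id[i] <- tpl$template_id
          out$epsilon[i] <- cl$epsilon
          out$rmsd_ca[i] <- cl$rmsd_ca
          if (sc > 0) {
            out$theta_x[i] <- theta[1]; out$theta_y[i] <- theta[2]
            out$theta_z[i] <- theta[3]
          } else {
            out$theta_x[i] <- out$theta_y[i] <- out$theta_z[i] <- NA_real_
          }
        }
      }
    }
  }
  out
}

#' Cross-moiety proximity boost
#'
#' Residue i's score is raised by the pre-boost score of every other
#' scored residue k whose predicted ligand center lies within
#' `range[1]`..`range[2]` Angstrom (inclusive) of residue i's and whose
#' moiety differs.  Sums use the pre-boost snapshot (no cascading);
#' residues without a positive base score are unchanged.
#'
#' @param predictions data.frame from [residue_binding_scores()].
#' @param range inclusive distance window, default `c(3, 9)`.
#' @param mode `"sum"` (add all qualifying scores) or `"max_single"`
#'   (add only the largest).
#' @return the data.frame with a `score_boosted` column added.
#' @export
apply_moiety_boost <- function(predictions, range = c(3, 9), mode = c("sum", "max_single")) {
  mode <- match.arg(mode)
  base <- predictions$score
  boosted <- base
  active <- which(base > 0 & !is.na(predictions$theta_x))
  if (length(active) >= 2) {
    th <- as.matrix(predictions[active, c("theta_x", "theta_y", "theta_z")])
    mo <- predictions$moiety[active]
    d <- as.matrix(dist(th))
    for (a in seq_along(active)) {
      ok <- which(d[a, ] >= range[1] & d[a, ] <= range[2] & mo != mo[a])
      ok <- setdiff(ok, a)
      if (!length(ok)) next
      add <- base[active[ok]]
      boosted[active[a]] <- base[active[a]] +
        if (mode == "sum") sum(add) else max(add)
    }
  }
  predictions$score_boosted <- boosted
  predictions
}

#' Z-normalize binding scores within one query protein
#'
#' @param scores numeric vector of per-residue scores (length >= 2).
#' @return z-scores (mean 0, sample SD 1).
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 residues to normalize")
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    stop(structure(class = c("fragsite_degenerate_scores", "error", "condition"),
                   list(message = "all binding scores equal; z-scores undefined",
                        call = sys.call(-1))))
  }
  (scores - mean(scores)) / s
}

#' Full scoring pipeline for one chain
#'
#' [residue_binding_scores()], then [apply_moiety_boost()], then
#' per-protein z-normalization and a binary call at `z_threshold`.  A
#' degenerate chain (all scores equal) gets `NA` z-scores and no calls.
#'
#' @param chain list of residue units with `ss` set.
#' @param db a `template_database`.
#' @param params overrides of [default_params()].
#' @return prediction data.frame with `score_boosted`, `z` and `call`.
#' @export
score_chain <- function(chain, db, params = list()) {
  p <- merge_params(params)
  pred <- residue_binding_scores(chain, db, params)
  pred <- apply_moiety_boost(pred, range = p$boost_range, mode = p$boost_mode)
  z <- tryCatch(normalize_scores(pred$score_boosted),
                fragsite_degenerate_scores = function(e) {
                  warning(conditionMessage(e), call. = FALSE)
                  rep(NA_real_, nrow(pred))
                })
  pred$z <- z
  pred$call <- !is.na(z) & z >= p$z_threshold
  pred
}
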