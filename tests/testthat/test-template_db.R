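test_that("moiety partitions cover NAD (44) and FAD (53) heavy atoms disjointly", {
  for (spec in list(list(code = "NAD", n = 44), list(code = "FAD", n = 53))) {
    part <- moiety_partition(spec$code)
    expect_length(part, 3)
    all_atoms <- unlist(part)
    expect_length(all_atoms, spec$n)
    expect_equal(anyDuplicated(all_atoms), 0L)
  }
  expect_error(moiety_partition("ATP"), "unsupported")
})

test_that("partition_ligand_moieties computes geometric centers", {
  # one atom per moiety: centers equal atom coordinates
  lig <- list(ligand_code = "NAD", chain_id = "A", het_seq = 1L,
              atoms = data.frame(name = c("C2N", "N9A", "PA"),
                                 element = c("C", "N", "P"),
                                 x = c(0, 10, 5), y = c(0, 0, 3), z = c(1, 2, 3)))
  mo <- partition_ligand_moieties(lig)
  expect_equal(unname(mo$nicotinamide$center), c(0, 0, 1))
  expect_equal(unname(mo$adenosine$center), c(10, 0, 2))
  expect_equal(unname(mo$phosphate$center), c(5, 3, 3))

  # mean of several phosphate atoms incl. the bridging O
  lig2 <- list(ligand_code = "NAD", chain_id = "A", het_seq = 1L,
               atoms = data.frame(name = c("PA", "PN", "O3"),
                                  element = c("P", "P", "O"),
                                  x = c(0, 2, 1), y = 0, z = 0))
  suppressWarnings(mo2 <- partition_ligand_moieties(lig2))
  expect_equal(unname(mo2$phosphate$center), c(1, 0, 0))

  # unrecognized atom name goes to the nearest moiety center
  lig3 <- lig
  lig3$atoms <- rbind(lig3$atoms,
                      data.frame(name = "XX9", element = "C",
                                 x = 9.5, y = 0, z = 2))
  expect_warning(mo3 <- partition_ligand_moieties(lig3), "unrecognized")
  expect_true("XX9" %in% mo3$adenosine$atom_names)

  bad <- lig
  bad$atoms$name <- c("Q1", "Q2", "Q3")
  expect_error(suppressWarnings(partition_ligand_moieties(bad)), "partition error")
  expect_error(partition_ligand_moieties(list(ligand_code = "GTP",
                                              atoms = lig$atoms)), "unsupported")
})

test_that("identify_binding_residues applies the distance cutoff exactly", {
  trip_at <- function(d) base_triplet() + matrix(c(d, 0, 0), 3, 3, byrow = TRUE)
  mk_res <- function(trip, pos) {
    list(chain_id = "A", seq_pos = pos, icode = "", seq_key = as.character(pos),
         res_name = "GLY", one_letter = "G",
         atoms = data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
                            x = trip[, 1], y = trip[, 2], z = trip[, 3]),
         triplet = trip, ss = "-")
  }
  moiety <- list(moiety = "phosphate", atom_names = "PA",
                 atoms = data.frame(name = "PA", element = "P",
                                    x = 0, y = 0, z = 0))
  # nearest atom is N at x = d - 1.458
  chain <- list(mk_res(trip_at(3.4 + 1.458), 1), mk_res(trip_at(3.6 + 1.458), 2))
  expect_equal(identify_binding_residues(chain, moiety, cutoff = 3.5), "1")
  # annotation intersects the geometric set
  ann <- list(pdb_id = "x", chain_id = "A", ligand_code = "NAD",
              binding_positions = c("2", "7"))
  expect_length(identify_binding_residues(chain, moiety, ann, cutoff = 3.5), 0)
  expect_error(identify_binding_residues(list(), moiety), "empty")
})

test_that("geometric identification matches a brute-force scan on planted fixtures", {
  toy <- cached_toy(2, seed = 101)
  e <- toy$entries[[1]]
  lig <- e$model$ligands[[1]]
  chain <- e$model$chains$A
  for (mo in partition_ligand_moieties(lig)) {
    got <- identify_binding_residues(chain, mo, cutoff = 3.5)
    # oracle: all-pairs atom distance scan
    lm <- as.matrix(mo$atoms[, c("x", "y", "z")])
    want <- vapply(chain, function(r) {
      ra <- as.matrix(r$atoms[, c("x", "y", "z")])
      any(apply(ra, 1, function(p) {
        any(sqrt(colSums((t(lm) - p)^2)) <= 3.5)
      }))
    }, logical(1))
    expect_setequal(got, vapply(chain, `[[`, character(1), "seq_key")[want])
    # planted residues of this moiety are recovered
    expect_true(all(e$planted[[mo$moiety]] %in% got))
  }
})

test_that("build_templates enforces the >=2 residue rule and records moieties", {
  toy <- cached_toy(2, seed = 5, noise_range = c(0, 0))
  db <- toy$db
  expect_s3_class(db, "template_database")
  expect_length(db$templates, 6) # 2 proteins x 3 moieties
  for (tpl in db$templates) {
    expect_gte(length(tpl$residues), 2)
    expect_true(all(vapply(tpl$residues, function(r) is.matrix(r$triplet), logical(1))))
  }
  # noise-free round trip: template residue sets equal the planted sets
  for (i in 1:2) {
    e <- toy$entries[[i]]
    mine <- Filter(function(t) tolower(t$pdb_id) == e$model$pdb_id, db$templates)
    expect_length(mine, 3)
    for (tpl in mine) {
      expect_setequal(vapply(tpl$residues, `[[`, character(1), "seq_key"),
                      e$planted[[tpl$moiety]])
    }
  }
  # a moiety with a single contacting residue yields no template
  e <- toy$entries[[1]]
  model <- e$model
  keep <- e$planted$phosphate[1]
  drop <- setdiff(unlist(e$planted), keep)
  model$chains$A <- Filter(function(r) !(r$seq_key %in% drop), model$chains$A)
  expect_warning(db1 <- build_templates(model), "no binding template")
  expect_length(db1$templates, 0)
  model$ligands <- list()
  expect_error(build_templates(model), "no supported ligand")
})

test_that("template database round-trips through JSON lines exactly", {
  toy <- cached_toy(2, seed = 9)
  db <- toy$db
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_template_db(db, path)
  back <- read_template_db(path)
  expect_equal(back$ligand_kind, db$ligand_kind)
  expect_length(back$templates, length(db$templates))
  for (k in seq_along(db$templates)) {
    a <- db$templates[[k]]; b <- back$templates[[k]]
    expect_equal(b$template_id, a$template_id)
    expect_equal(b$moiety, a$moiety)
    expect_equal(b$ligand_center, a$ligand_center, tolerance = 1e-12)
    for (r in seq_along(a$residues)) {
      expect_equal(unname(b$residues[[r]]$triplet), unname(a$residues[[r]]$triplet),
                   tolerance = 1e-12)
      expect_equal(b$residues[[r]]$res_name, a$residues[[r]]$res_name)
    }
  }
  # corrupted residue count is detected and names the template
  lines <- readLines(path)
  bad <- sub('"n_residues":[0-9]+', '"n_residues":99', lines[2])
  writeLines(c(lines[1], bad, lines[-(1:2)]), path)
  expect_error(read_template_db(path), "corrupted residue count")
  # version mismatch
  writeLines(c(sub('"version":1', '"version":2', lines[1]), lines[-1]), path)
  expect_error(read_template_db(path), "version mismatch")
  expect_error(read_template_db(file.path(tempdir(), "missing.jsonl")), "not found")
})

test_that("read_biolip_annotations parses residue tokens", {
  anns <- read_biolip_annotations("1dxy A NAD G12 R15 D37")
  expect_length(anns, 1)
  expect_setequal(anns[[1]]$binding_positions, c("12", "15", "37"))
  expect_equal(anns[[1]]$ligand_code, "NAD")

  expect_warning(empty <- read_biolip_annotations("1abc B FAD"), "empty")
  expect_length(empty[[1]]$binding_positions, 0)

  dup <- read_biolip_annotations(c("1dxy A NAD G12 R15", "1dxy A NAD G12 R15"))
  expect_length(dup, 1)

  expect_warning(skipped <- read_biolip_annotations("1dxy A NAD G12 ??"),
                 "unparseable")
  expect_length(skipped, 0)
})

test_that("binding_composition_stats counts frequencies and atom contacts", {
  # 10-residue all-glycine chain, 2-residue glycine template
  chain <- generate_ideal_backbone(10, strrep("-", 10),
                                   sequence = strrep("G", 10), seed = 1)
  model <- structure(list(pdb_id = "gly", chains = list(A = chain),
                          ligands = list()), class = "structure_model")
  db <- structure(list(
    ligand_kind = "NAD",
    templates = list(list(template_id = "t1", pdb_id = "gly", chain_id = "A",
                          het_seq = 1L, moiety = "phosphate",
                          ligand_center = c(0, 0, 0),
                          residues = lapply(1:2, function(i) {
                            list(seq_key = as.character(i), res_name = "GLY",
                                 one_letter = "G", ss = "-",
                                 triplet = chain[[i]]$triplet)
                          }))),
    provenance = list()), class = "template_database")
  st <- binding_composition_stats(db, list(model))
  row <- st$residue_stats[st$residue_stats$res_name == "GLY", ]
  expect_equal(row$binding_freq, 1.0)
  expect_equal(row$whole_freq, 1.0)
  expect_equal(row$ratio, 1.0)
  expect_error(binding_composition_stats(
    structure(list(ligand_kind = "NAD", templates = list()),
              class = "template_database"), list(model)), "empty")

  # serine enrichment: 3 SER among 5 binders, SER whole-frequency 0.10
  seq20 <- paste(c(rep("S", 2), rep("A", 18)), collapse = "")
  chain2 <- generate_ideal_backbone(20, strrep("-", 20), sequence = seq20, seed = 2)
  model2 <- structure(list(pdb_id = "ser", chains = list(A = chain2),
                           ligands = list()), class = "structure_model")
  mk_res <- function(rn) list(seq_key = "1", res_name = rn,
                              one_letter = residue_one_letter(rn), ss = "-",
                              triplet = chain2[[1]]$triplet)
  db2 <- db
  db2$templates <- list(list(template_id = "t2", pdb_id = "ser", chain_id = "A",
                             het_seq = 1L, moiety = "phosphate",
                             ligand_center = c(0, 0, 0),
                             residues = c(lapply(1:3, function(i) mk_res("SER")),
                                          lapply(1:2, function(i) mk_res("ALA")))))
  st2 <- binding_composition_stats(db2, list(model2))
  ser <- st2$residue_stats[st2$residue_stats$res_name == "SER", ]
  expect_equal(ser$binding_freq, 0.6)
  expect_equal(ser$whole_freq, 0.1)
  expect_equal(ser$ratio, 6.0)

  # atom contacts: backbone N at 3.4 A counted, side-chain OG at 3.6 A not
  res <- chain[[1]]
  res$atoms <- data.frame(name = c("N", "OG"), element = c("N", "O"),
                          x = c(3.4, 3.6), y = 0, z = 0)
  model3 <- structure(list(
    pdb_id = "at", chains = list(A = list(res)),
    ligands = list(list(ligand_code = "NAD", chain_id = "A", het_seq = 1L,
                        atoms = data.frame(name = "PA", element = "P",
                                           x = 0, y = 0, z = 0)))),
    class = "structure_model")
  suppressWarnings(st3 <- binding_composition_stats(db, list(model3)))
  expect_equal(nrow(st3$atom_stats), 1)
  expect_equal(st3$atom_stats$element, "N")
  expect_true(st3$atom_stats$backbone)
  expect_equal(st3$atom_stats$count, 1L)
})
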