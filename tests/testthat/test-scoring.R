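test_that("rmsd_component follows 1/(1+r) with hard rejection at 3 A", {
  expect_equal(rmsd_component(0), 1.0)
  expect_equal(rmsd_component(1.0), 0.5)
  expect_true(is.na(rmsd_component(3.0)))
  expect_true(is.na(rmsd_component(10)))
  expect_error(rmsd_component(-0.1), "negative")
  # surviving clusters always score in (0.25, 1]
  r <- seq(0, 2.99, by = 0.01)
  v <- rmsd_component(r)
  expect_true(all(v > 0.25 & v <= 1))
  # monotone: larger RMSD never scores higher
  expect_true(all(diff(v) < 0))
})

test_that("blosum_component matches hand-computed sums", {
  # G/G = 6: raw 12, normalized 12/13
  b <- blosum_component(cbind(c("G", "G"), c("G", "G")))
  expect_equal(b$raw, 12)
  expect_equal(b$score, 12 / 13)
  # query GV vs template GA: G/G=6, V/A=0 -> raw 6; self G+A = 10 -> 6/11
  b2 <- blosum_component(cbind(c("G", "V"), c("G", "A")))
  expect_equal(b2$raw, 6)
  expect_equal(b2$score, 6 / 11)
  expect_error(blosum_component(cbind("G", "~")), "unknown residue symbol")
})

test_that("dssp_component scores 3-state collapsed labels", {
  d <- dssp_component(cbind(c("H", "H"), c("H", "H")))
  expect_equal(d$raw, 4)
  expect_equal(d$score, 4 / 5)
  d2 <- dssp_component(cbind(c("H", "E"), c("H", "H")))
  expect_equal(d2$raw, 1)
  expect_equal(d2$score, 1 / 5)
  # 8-state inputs collapse: G counts as helix, B as strand
  d3 <- dssp_component(cbind(c("G", "B"), c("H", "E")))
  expect_equal(d3$raw, 4)
  # identical labels give the maximal score for that template
  set.seed(1)
  for (rep in 1:10) {
    t_lab <- sample(c("H", "E", "-"), 4, replace = TRUE)
    self <- dssp_component(cbind(t_lab, t_lab))$score
    q_lab <- sample(c("H", "E", "-"), 4, replace = TRUE)
    expect_lte(dssp_component(cbind(q_lab, t_lab))$score, self)
  }
})

# a template of two glycine helix residues and its exact source chain
self_match_fixture <- function() {
  chain <- generate_ideal_backbone(8, strrep("H", 8),
                                   sequence = strrep("G", 8), seed = 3)
  chain <- lapply(chain, function(r) { r$ss <- "H"; r })
  tpl <- list(template_id = "src1_A_NAD1_phosphate", pdb_id = "src1",
              chain_id = "A", het_seq = 1L, moiety = "phosphate",
              ligand_center = c(5, 5, 5),
              residues = lapply(chain[c(3, 6)], function(r) {
                list(seq_key = r$seq_key, res_name = r$res_name,
                     one_letter = "G", ss = "H", triplet = r$triplet)
              }))
  db <- structure(list(ligand_kind = "NAD", templates = list(tpl),
                       provenance = list()), class = "template_database")
  list(chain = chain, db = db, tpl = tpl)
}

test_that("self-match composite score is epsilon * C^R * C^B * C^D", {
  fx <- self_match_fixture()
  pred <- residue_binding_scores(fx$chain, fx$db)
  expected <- 2 * 1 * (12 / 13) * (4 / 5)
  hit <- pred[pred$seq_key %in% c("3", "6"), ]
  expect_equal(hit$score, rep(expected, 2), tolerance = 1e-9)
  expect_equal(hit$moiety, rep("phosphate", 2))
  # predicted center back-projects the template ligand center exactly
  expect_equal(unname(as.matrix(hit[, c("theta_x", "theta_y", "theta_z")])),
               matrix(5, 2, 3), tolerance = 1e-6)
  # an ideal helix is self-similar, so offset pairs may also match the
  # template -- but never better than the exact self-match
  expect_true(all(pred$score <= expected + 1e-9))
  expect_true(all(is.na(pred$theta_x[pred$score == 0])))
  expect_true(all(!is.na(pred$theta_x[pred$score > 0])))
})

test_that("the per-residue score is the max over clusters of all templates", {
  fx <- self_match_fixture()
  # second template: same geometry but alanines (lower BLOSUM component)
  tpl2 <- fx$tpl
  tpl2$template_id <- "src2_A_NAD1_adenosine"
  tpl2$pdb_id <- "src2"
  tpl2$moiety <- "adenosine"
  tpl2$residues <- lapply(tpl2$residues, function(r) {
    r$res_name <- "ALA"; r$one_letter <- "A"; r
  })
  db <- fx$db
  db$templates <- c(db$templates, list(tpl2))
  pred <- residue_binding_scores(fx$chain, db)
  hit <- pred[pred$seq_key == "3", ]
  # G vs A scores 0: raw 0 -> the glycine template must win
  expect_equal(hit$score, 2 * (12 / 13) * (4 / 5), tolerance = 1e-9)
  expect_equal(hit$template_id, "src1_A_NAD1_phosphate")
  # leave-one-out exclusion removes the winning template
  pred2 <- residue_binding_scores(fx$chain, db, list(exclude_pdb = "src1"))
  expect_equal(pred2$template_id[pred2$seq_key == "3"], "src2_A_NAD1_adenosine")
})

test_that("self-match dominates noise-perturbed template copies", {
  fx <- self_match_fixture()
  pred0 <- residue_binding_scores(fx$chain, fx$db)
  base_score <- max(pred0$score)
  set.seed(99)
  for (rep in 1:100) {
    tplp <- fx$tpl
    tplp$template_id <- paste0("pert", rep)
    tplp$pdb_id <- paste0("p", rep)
    tplp$residues <- lapply(tplp$residues, function(r) {
      r$triplet <- r$triplet + matrix(rnorm(9, 0, 0.5), 3, 3)
      r
    })
    db <- structure(list(ligand_kind = "NAD", templates = list(tplp),
                         provenance = list()), class = "template_database")
    predp <- residue_binding_scores(fx$chain, db)
    expect_lte(max(predp$score), base_score + 1e-12)
  }
})

boost_fixture <- function(score_a, score_b, dist, moiety_b = "phosphate") {
  data.frame(chain_id = "A", seq_key = c("1", "2"), seq_pos = 1:2,
             res_name = "GLY", score = c(score_a, score_b),
             moiety = c("adenosine", moiety_b),
             theta_x = c(0, dist), theta_y = 0, theta_z = 0,
             template_id = "t", epsilon = 2L, rmsd_ca = 0,
             stringsAsFactors = FALSE)
}

test_that("moiety boost fires only across moieties within [3, 9] A", {
  b <- apply_moiety_boost(boost_fixture(1.0, 0.5, 6))
  expect_equal(b$score_boosted, c(1.5, 1.5))
  # below 3 A: unchanged
  expect_equal(apply_moiety_boost(boost_fixture(1.0, 0.5, 2))$score_boosted,
               c(1.0, 0.5))
  # beyond 9 A: unchanged
  expect_equal(apply_moiety_boost(boost_fixture(1.0, 0.5, 9.5))$score_boosted,
               c(1.0, 0.5))
  # equal moiety: unchanged
  expect_equal(apply_moiety_boost(boost_fixture(1.0, 0.5, 6, "adenosine"))$score_boosted,
               c(1.0, 0.5))
  # inclusive bounds
  expect_equal(apply_moiety_boost(boost_fixture(1.0, 0.5, 3))$score_boosted,
               c(1.5, 1.5))
  expect_equal(apply_moiety_boost(boost_fixture(1.0, 0.5, 9))$score_boosted,
               c(1.5, 1.5))
  # zero-score residues receive no boost
  z <- apply_moiety_boost(boost_fixture(0, 0.5, 6))
  expect_equal(z$score_boosted[1], 0)
  # max_single mode adds only the largest qualifying score
  three <- rbind(boost_fixture(1.0, 0.5, 6),
                 boost_fixture(0.2, 0.2, 6)[2, ])
  three$seq_key <- as.character(1:3); three$seq_pos <- 1:3
  three$moiety <- c("adenosine", "phosphate", "nicotinamide")
  three$theta_x <- c(0, 6, 4)
  s <- apply_moiety_boost(three, mode = "sum")
  m <- apply_moiety_boost(three, mode = "max_single")
  expect_equal(s$score_boosted[1], 1.0 + 0.5 + 0.2)
  expect_equal(m$score_boosted[1], 1.0 + 0.5)
})

test_that("boost uses the pre-boost snapshot and is order-independent", {
  set.seed(17)
  n <- 30
  pred <- data.frame(chain_id = "A", seq_key = as.character(1:n), seq_pos = 1:n,
                     res_name = "GLY",
                     score = round(runif(n, 0, 2), 3) * rbinom(n, 1, 0.7),
                     moiety = sample(c("adenosine", "phosphate", "nicotinamide"),
                                     n, replace = TRUE),
                     theta_x = runif(n, 0, 15), theta_y = runif(n, 0, 15),
                     theta_z = runif(n, 0, 15),
                     template_id = "t", epsilon = 2L, rmsd_ca = 0,
                     stringsAsFactors = FALSE)
  pred$theta_x[pred$score == 0] <- NA
  ref <- apply_moiety_boost(pred)
  for (rep in 1:5) {
    perm <- sample(n)
    got <- apply_moiety_boost(pred[perm, ])
    expect_equal(got$score_boosted[order(perm)], ref$score_boosted)
  }
  # no cascading: boosting twice from the snapshot differs from re-boosting
  expect_equal(ref$score_boosted,
               pred$score + (apply_moiety_boost(pred)$score_boosted - pred$score))
})

test_that("normalize_scores yields exact z-scores", {
  expect_equal(normalize_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(5:50, 1), sd = runif(1, 0.1, 10))
    z <- normalize_scores(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
  expect_error(normalize_scores(rep(2, 10)), "all binding scores equal")
  expect_error(normalize_scores(1), "at least 2")
  # degenerate chains are flagged and produce no calls
  chain <- generate_ideal_backbone(10, strrep("-", 10), seed = 8)
  db <- structure(list(ligand_kind = "NAD", templates = list(),
                       provenance = list()), class = "template_database")
  expect_warning(pred <- score_chain(chain, db), "all binding scores equal")
  expect_true(all(!pred$call))
})
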