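two_atom_models <- function(d, n_models = 1) {
  lapply(seq_len(n_models), function(m)
    data.frame(chain = c("S", "P"), residue_number = c(1L, 50L),
               residue_name = c("ALA", "GLY"), atom_name = c("CA", "CA"),
               x = c(0, d), y = c(0, 0), z = c(0, 0),
               element = c("C", "C"), stringsAsFactors = FALSE))
}

test_that("PDB ensembles round-trip through the writer and bio3d parser", {
  set.seed(17)
  models <- lapply(1:2, function(m) {
    data.frame(chain = rep(c("S", "P"), c(2, 3)),
               residue_number = c(1L, 2L, 10L, 11L, 12L),
               residue_name = c("ALA", "GLU", "GLY", "SER", "LYS"),
               atom_name = c("CA", "CB", "CA", "OG", "NZ"),
               x = round(runif(5, -20, 20), 3), y = round(runif(5, -20, 20), 3),
               z = round(runif(5, -20, 20), 3),
               element = c("C", "C", "C", "O", "N"), stringsAsFactors = FALSE)
  })
  ens <- parse_ensemble(write_ensemble(models))
  expect_equal(ens$n_models, 2L)
  expect_equal(nrow(ens$atoms), 5L)
  expect_equal(ens$atoms$chain, models[[1]]$chain)
  expect_equal(ens$atoms$residue_number, models[[1]]$residue_number)
  expect_equal(ens$atoms$atom_name, models[[1]]$atom_name)
  for (m in 1:2) {
    co <- matrix(ens$xyz[m, ], ncol = 3, byrow = TRUE)
    expect_equal(co, as.matrix(models[[m]][, c("x", "y", "z")]),
                 ignore_attr = TRUE, tolerance = 1e-9)  # 3-decimal format
  }
  # no MODEL keywords -> single model
  single <- parse_ensemble(write_ensemble(models[1]))
  expect_equal(single$n_models, 1L)
  expect_error(parse_ensemble(c("HEADER junk", "END")), "empty structure")
})

test_that("hydrogens are excluded by default", {
  m <- data.frame(chain = c("S", "P", "P"), residue_number = c(1L, 2L, 2L),
                  residue_name = c("ALA", "GLY", "GLY"),
                  atom_name = c("CA", "CA", "HA"),
                  x = c(0, 3, 3.2), y = 0, z = 0,
                  element = c("C", "C", "H"), stringsAsFactors = FALSE)
  ens <- parse_ensemble(write_ensemble(list(m)))
  expect_equal(nrow(ens$atoms), 2L)
  ens_h <- parse_ensemble(write_ensemble(list(m)), keep_hydrogens = TRUE)
  expect_equal(nrow(ens_h$atoms), 3L)
})

test_that("contact cutoff is inclusive at exactly 4 Angstrom", {
  at4 <- parse_ensemble(write_ensemble(two_atom_models(4.0)))
  expect_equal(nrow(interchain_contacts(at4, "S", "P")), 1L)
  expect_equal(interchain_contacts(at4, "S", "P")$distance, 4.0)
  just_out <- parse_ensemble(write_ensemble(two_atom_models(4.001)))
  expect_equal(nrow(interchain_contacts(just_out, "S", "P")), 0L)
  expect_error(interchain_contacts(at4, "S", "Q"), "chain not found")
})

test_that("contacts match an exhaustive pairwise oracle and chain symmetry", {
  # planted grid: 3 peptide atoms, each within 4 A of exactly 2 protein atoms
  pep <- data.frame(chain = "S", residue_number = 1:3, residue_name = "ALA",
                    atom_name = c("CA", "CB", "CG"),
                    x = c(0, 50, 100), y = 0, z = 0, element = "C",
                    stringsAsFactors = FALSE)
  prot <- data.frame(chain = "P", residue_number = 101:106, residue_name = "GLY",
                     atom_name = "CA",
                     x = rep(c(0, 50, 100), each = 2), y = rep(c(3, -3), 3),
                     z = 0, element = "C", stringsAsFactors = FALSE)
  ens <- parse_ensemble(write_ensemble(list(rbind(pep, prot))))
  cc <- interchain_contacts(ens, "S", "P")
  expect_equal(nrow(cc), 6L)
  # oracle: brute-force over every atom pair
  co <- matrix(ens$xyz[1, ], ncol = 3, byrow = TRUE)
  n_oracle <- 0L
  for (i in which(ens$atoms$chain == "S"))
    for (j in which(ens$atoms$chain == "P"))
      if (sqrt(sum((co[i, ] - co[j, ])^2)) <= 4) n_oracle <- n_oracle + 1L
  expect_equal(nrow(cc), n_oracle)
  # symmetry up to record transposition
  rev <- interchain_contacts(ens, "P", "S")
  expect_equal(nrow(rev), nrow(cc))
  expect_equal(sort(rev$distance), sort(cc$distance))
})

test_that("position-to-sum statistics follow the counting rules", {
  mk <- function(model_id, res, pat, pres, patom)
    data.frame(model_id = model_id, peptide_residue = res, peptide_atom = pat,
               protein_residue = pres, protein_atom = patom, distance = 3.5,
               stringsAsFactors = FALSE)
  # one pair in 1 of 10 models -> positions 1, sum 1, ratio 1
  s1 <- position_to_sum(mk(3, 5, "CB", 200, "CA"))
  expect_equal(s1$position_contacts, 1L)
  expect_equal(s1$sum_contacts, 1L)
  expect_equal(s1$ratio, 1)
  # residue with no contacts anywhere -> ratio 0
  s0 <- position_to_sum(mk(1, 5, "CB", 200, "CA"), peptide_residues = c(5, 9))
  expect_equal(s0$ratio[s0$peptide_residue == 9], 0)
  # two distinct pairs, one in 3 models, one in 1 -> positions 2, sum 4, ratio 2
  cc <- rbind(mk(1, 7, "CB", 200, "CA"), mk(2, 7, "CB", 200, "CA"),
              mk(3, 7, "CB", 200, "CA"), mk(2, 7, "CG", 201, "CA"))
  s2 <- position_to_sum(cc)
  expect_equal(s2$position_contacts, 2L)
  expect_equal(s2$sum_contacts, 4L)
  expect_equal(s2$ratio, 2.0)
  # duplicating every model doubles sums, keeps positions
  dup <- rbind(cc, transform(cc, model_id = model_id + 10))
  sd2 <- position_to_sum(dup)
  expect_equal(sd2$sum_contacts, 2L * s2$sum_contacts)
  expect_equal(sd2$position_contacts, s2$position_contacts)
  expect_gte(sum(sd2$sum_contacts), sum(sd2$position_contacts))
})

test_that("residue classes map ratio 0 / 1 / >1 to none / unique / recurrent", {
  s <- data.frame(peptide_residue = 1:3, position_contacts = c(0L, 2L, 2L),
                  sum_contacts = c(0L, 2L, 3L), ratio = c(0, 1, 1.5))
  cl <- classify_residues(s)
  expect_equal(cl$class, c("none", "unique", "recurrent"))
})
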