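test_that("parse_structure reads a minimal two-chain PDB and keeps only heavy polymer atoms", {
  path <- write_minimal_pdb(tempfile(fileext = ".pdb"))
  s <- parse_structure(path, model_id = "mini")
  expect_s3_class(s, "cl_structure")
  expect_identical(s$chains, c("A", "B"))
  expect_identical(nrow(structure_residues(s)), 2L)
  expect_identical(nrow(s$atoms), 4L)

  # hydrogens are dropped, leaving an identical structure
  path_h <- write_minimal_pdb(tempfile(fileext = ".pdb"),
                              with_hydrogen = TRUE)
  s_h <- suppressMessages(parse_structure(path_h, model_id = "mini"))
  expect_equal(s_h$atoms, s$atoms)

  # waters / HETATM records are dropped
  path_w <- write_minimal_pdb(tempfile(fileext = ".pdb"), with_water = TRUE)
  s_w <- parse_structure(path_w, model_id = "mini")
  expect_equal(s_w$atoms, s$atoms)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- write_minimal_pdb(tempfile(fileext = ".pdb"), with_altloc = TRUE)
  s <- suppressMessages(parse_structure(path))
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_identical(nrow(cb), 1L)
  expect_equal(cb$x, 1.5)  # occupancy 0.6 conformer, not the 0.4 one
})

test_that("only the first MODEL of a multi-model file is read", {
  path <- write_minimal_pdb(tempfile(fileext = ".pdb"), second_model = TRUE)
  s <- parse_structure(path)
  expect_identical(nrow(s$atoms), 4L)
  expect_true(all(s$atoms$x < 90))
})

test_that("parse_structure rejects unreadable and empty inputs", {
  expect_error(parse_structure(tempfile()), "not found")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), empty)
  expect_error(parse_structure(empty), "no protein ATOM")
})

test_that("partner specs split chains into two disjoint groups", {
  atoms <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(ch)
    data.frame(chain = ch, resno = 1L, insert = "", resid = "ALA",
               elety = "CA", element = "C", x = match(ch, LETTERS) * 5,
               y = 0, z = 0)))
  s4 <- clrescore:::new_structure("four", atoms)
  ps <- parse_partner_spec("AB_CD", s4)
  expect_identical(ps$group_a, c("A", "B"))
  expect_identical(ps$group_b, c("C", "D"))

  s2 <- clrescore:::new_structure("dimer", atoms[atoms$chain %in% c("A", "B"), ])
  s2$atoms$chain[s2$atoms$chain == "B"] <- "G"
  s2 <- clrescore:::new_structure("dimer", s2$atoms)
  ps2 <- parse_partner_spec("A_G", s2)
  expect_identical(ps2$group_a, "A")
  expect_identical(ps2$group_b, "G")

  expect_error(parse_partner_spec("A_A", s4), "both partners")
  expect_error(parse_partner_spec("ABCD", s4), "underscore")
  expect_error(parse_partner_spec("AB_CD_E", s4), "underscore")
  expect_error(parse_partner_spec("AB_CZ", s4), "not present")
  expect_error(parse_partner_spec("_AB", s4), "non-empty")
})

test_that("interface_distance is the minimum heavy-atom pair distance", {
  atoms <- data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1L, 2L, 1L, 1L), insert = "",
    resid = "ALA", elety = c("CA", "CA", "CA", "CB"), element = "C",
    x = c(0, 10, 3, 30), y = c(0, 0, 4, 0), z = 0)
  s <- clrescore:::new_structure("tri", atoms)
  ps <- parse_partner_spec("A_B", s)
  # 3-4-5 triangle: single-atom residue at origin, nearest partner at (3,4,0)
  expect_equal(interface_distance(s, ps, "A", 1), 5)

  # a residue's distance is the min over its own atoms too
  atoms2 <- rbind(atoms,
                  data.frame(chain = "A", resno = 1L, insert = "",
                             resid = "ALA", elety = "CB", element = "C",
                             x = 3, y = 11.2, z = 0))
  s2 <- clrescore:::new_structure("tri2", atoms2)
  ps2 <- parse_partner_spec("A_B", s2)
  expect_equal(interface_distance(s2, ps2, "A", 1), 5)

  expect_error(interface_distance(s, ps, "A", 99), "not found")
})

test_that("interface_distance matches the brute-force all-pairs oracle and is symmetric", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_toy_structure()
    ps <- parse_partner_spec("A_B", s)
    ps_swap <- ps
    ps_swap$group_a <- ps$group_b
    ps_swap$group_b <- ps$group_a
    res <- structure_residues(s)
    pick <- res[sample(nrow(res), 3), ]
    for (j in seq_len(nrow(pick))) {
      d <- interface_distance(s, ps, pick$chain[j], pick$resno[j])
      expect_equal(d, brute_force_interface_distance(s, ps, pick$chain[j],
                                                     pick$resno[j]),
                   tolerance = 1e-12)
      expect_equal(d, interface_distance(s, ps_swap, pick$chain[j],
                                         pick$resno[j]))
    }
  }
})

test_that("interface_distance is invariant under rigid motion and tracks separating translations", {
  set.seed(7)
  s <- make_toy_complex(8, seed = 3)
  ps <- parse_partner_spec("A_B", s)
  d0 <- interface_distance(s, ps, "A", 1)
  moved <- transform_structure(s, random_rotation(), c(5, -3, 12))
  expect_equal(interface_distance(moved, ps, "A", 1), d0, tolerance = 1e-9)

  # exactly axis-aligned partners: separating them along that axis grows the
  # minimum by exactly t
  aligned <- data.frame(chain = c("A", "B"), resno = 1L, insert = "",
                        resid = "GLY", elety = "CA", element = "C",
                        x = 0, y = 0, z = c(0, 10))
  s_ax <- clrescore:::new_structure("axis", aligned)
  ps_ax <- parse_partner_spec("A_B", s_ax)
  aligned$z[2] <- 17
  s_ax7 <- clrescore:::new_structure("axis7", aligned)
  expect_equal(interface_distance(s_ax7, ps_ax, "A", 1),
               interface_distance(s_ax, ps_ax, "A", 1) + 7)

  # toy complex, large separation: growth approaches +t from below
  at <- s$atoms
  base <- s
  at$z[at$chain == "B"] <- at$z[at$chain == "B"] + 40
  sep <- clrescore:::new_structure("sep", at)
  d_sep <- interface_distance(sep, ps, "A", 1)
  at$z[at$chain == "B"] <- at$z[at$chain == "B"] + 7
  sep7 <- clrescore:::new_structure("sep7", at)
  gain <- interface_distance(sep7, ps, "A", 1) - d_sep
  expect_lte(gain, 7)
  expect_gt(gain, 6.99)
  # and a translation by t never increases any distance by more than t
  res <- structure_residues(s)
  d_all0 <- interface_distances(base, ps, res)
  d_all <- interface_distances(sep, ps, res)
  expect_true(all(d_all - d_all0 <= 40 + 1e-9))
})

test_that("interface classification is inclusive at the cutoff", {
  expect_true(is_interface_residue(9.9, 10))
  expect_true(is_interface_residue(10.0, 10))
  expect_false(is_interface_residue(10.1, 10))
  expect_error(is_interface_residue(-1, 10), "negative")
})

test_that("ambiguous insertion codes are a lookup error, not a silent pick", {
  atoms <- data.frame(
    chain = c("A", "A", "B"), resno = c(5L, 5L, 1L),
    insert = c("", "A", ""), resid = "ALA", elety = "CA", element = "C",
    x = c(0, 1, 10), y = 0, z = 0)
  s <- clrescore:::new_structure("ins", atoms)
  ps <- parse_partner_spec("A_B", s)
  expect_error(interface_distance(s, ps, "A", 5), "insertion codes")
  expect_equal(interface_distance(s, ps, "A", 5, insert = "A"), 9)
})
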