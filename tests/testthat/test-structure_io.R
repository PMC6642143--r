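test_that("hand-written 3-atom PDB parses to a 1-residue model in nm", {
  pdb <- c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.000   2.500   3.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       3.000   3.000   3.500  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(m$residues), 1L)
  expect_equal(m$atoms$x, c(0.1, 0.2, 0.3))   # angstrom -> nm
  expect_equal(m$residues$name, "GLY")
})

test_that("water-only PDB triggers the empty-protein path", {
  pdb <- c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_error(read_structure(f), "no protein ATOM")
  expect_warning(res <- read_structure(f, on_empty = "warn"), "no protein ATOM")
  expect_null(res)
})

test_that("synthetic fixture PDB round-trips coordinates within PDB precision", {
  p <- make_ellipsoid_protein(tiny_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(p$model, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(p$model$atoms))
  expect_lt(max(abs(coords(m2) - coords(p$model))), 1e-3)  # nm
  expect_equal(m2$residues$chain, p$model$residues$chain)
})

test_that("GRO files parse with coordinates already in nm", {
  gro <- c("synthetic peptide", "  3",
           "    1GLY      N    1   0.100   0.200   0.300",
           "    1GLY     CA    2   0.200   0.250   0.300",
           "    2ALA     CA    3   0.500   0.500   0.500",
           "   2.00000   2.00000   2.00000")
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(m$residues), 2L)
  expect_equal(m$atoms$x, c(0.1, 0.2, 0.5))
})

test_that("gapless renumbering closes the documented 2-gap and 8-gap cases", {
  # beta-tubulin-like: 2 missing residues after Leu 44
  m <- peptide_model("LLLL", start_number = 43L)
  m$residues$number <- c(43L, 44L, 47L, 48L)
  g <- renumber_gapless(m)
  expect_equal(g$residues$number, 43:46)
  map <- attr(g, "renumber_map")
  expect_equal(map$author_number, c(43L, 44L, 47L, 48L))

  # 8 missing residues after Pro 360: successor becomes 361
  m2 <- peptide_model("PPGG", start_number = 358L)
  m2$residues$number <- c(358L, 359L, 360L, 369L)
  g2 <- renumber_gapless(m2)
  expect_equal(g2$residues$number[4], 361L)
})

test_that("gapless renumbering is idempotent and rejects duplicates", {
  m <- peptide_model("ACDEFG", start_number = 10L)
  m$residues$number <- c(10L, 11L, 15L, 16L, 20L, 21L)
  once <- renumber_gapless(m)
  twice <- renumber_gapless(once)
  expect_equal(twice$residues$number, once$residues$number)
  # already-consecutive chain: identity
  g <- renumber_gapless(peptide_model("ACDEFG"))
  expect_equal(g$residues$number, 1:6)
  dup <- peptide_model("AC")
  dup$residues$number <- c(5L, 5L)
  expect_error(renumber_gapless(dup), "duplicate")
})

test_that("pH-7 formal charges reproduce the CTT side-chain totals", {
  beta <- peptide_model("QDATADEQGEFEEEGEEDEA")  # beta-CTT: 3 Asp + 8 Glu
  expect_equal(assign_formal_charges(beta)$total, -11)
  alpha <- peptide_model("GVDSVEGEGEEEGEEY")     # alpha-CTT: 1 Asp + 7 Glu
  expect_equal(assign_formal_charges(alpha)$total, -8)
  expect_equal(assign_formal_charges(peptide_model("GGGGGG"))$total, 0)
})

test_that("formal charge totals match a counting oracle on random 20-mers", {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(aa, 20, replace = TRUE), collapse = "")
    m <- peptide_model(s)
    counts <- table(factor(strsplit(s, "")[[1]], levels = aa))
    oracle <- (counts[["K"]] + counts[["R"]]) - (counts[["D"]] + counts[["E"]])
    expect_equal(assign_formal_charges(m)$total, oracle)
    # whole-chain termini add +1 and -1, i.e. leave the total unchanged
    expect_equal(assign_formal_charges(m, termini = TRUE)$total, oracle)
  }
})

test_that("histidine charge is configurable", {
  m <- peptide_model("HHH")
  expect_equal(assign_formal_charges(m)$total, 0)
  expect_equal(assign_formal_charges(m, his_charge = 1)$total, 3)
})

test_that("partial charge tables align to atoms and name missing ones", {
  m <- point_model(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(atom_serial = c(2, 1, 3), charge = c(0.5, -1, 0.5)),
            f, row.names = FALSE)
  ca <- load_partial_charges(f, m)
  expect_equal(ca$charges, c(-1, 0.5, 0.5))  # model atom order
  expect_equal(ca$total, 0)
  write.csv(data.frame(atom_serial = c(1, 2), charge = c(0.5, -1)),
            f, row.names = FALSE)
  expect_error(load_partial_charges(f, m), "serial: 3")
})

test_that("a CTT-like charge table totals -11 within 1e-9 e", {
  m <- peptide_model("QDATADEQGEFEEEGEEDEA")
  q <- assign_formal_charges(m)$charges
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(atom_serial = m$atoms$serial, charge = q + 1e-13),
            f, row.names = FALSE)
  ca <- load_partial_charges(f, m)
  expect_equal(ca$total, -11, tolerance = 1e-9)
})

test_that("select_ctt returns the final residues with the default lengths", {
  core <- paste(rep("A", 30), collapse = "")
  alpha <- peptide_model(paste0(core, "GVDSVEGEGEEEGEEY"), chain = "A")
  sel <- select_ctt(alpha, "A")
  expect_s3_class(sel, "residue_selection")
  expect_equal(nrow(sel), 16L)
  expect_equal(selection_sequence(alpha, sel), "GVDSVEGEGEEEGEEY")
  beta <- peptide_model(paste0(core, "QDATADEQGEFEEEGEEDEA"), chain = "B")
  selb <- select_ctt(beta, "B")
  expect_equal(nrow(selb), 20L)
  expect_equal(selection_sequence(beta, selb), "QDATADEQGEFEEEGEEDEA")
  short <- peptide_model("AAAAAAAAAA", chain = "A")
  expect_error(select_ctt(short, "A", length = 16), "fewer")
})

test_that("packaged site definitions carry the documented residues", {
  sites <- load_site_definitions()
  pac <- sites[["paclitaxel-site"]]
  expect_true(all(c(215, 280, 361) %in% pac$number[pac$chain == "B"]))
  col <- sites[["colchicine-site"]]
  expect_true(180 %in% col$number[col$chain == "A"])
  expect_true(246 %in% col$number[col$chain == "B"])
  expect_equal(sites[["gtp-hydrolysis"]]$number, 251)
  expect_equal(sites[["vinca-site"]]$chain, c("A", "B"))
  # empty config -> empty list; binding against a model without the residues errors
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", f)
  expect_length(load_site_definitions(f), 0L)
  tiny <- peptide_model("AAA")
  expect_error(load_site_definitions(model = tiny), "absent from model")
})
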