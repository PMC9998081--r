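test_that("parse_pdb reads residues in file order with 0-based indices", {
  f <- parse_pdb(fixture_two_res())
  expect_s3_class(f, "fold")
  expect_equal(length(f), 2L)
  expect_equal(f$chains, "A")
  r <- residues(f)
  expect_equal(r$index, c(0L, 1L))
  expect_equal(r$res_name, c("GLY", "ALA"))
  expect_equal(r$author_number, c(1L, 2L))
})

test_that("parse_pdb handles paths, strings, and bad input", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_two_res(), path)
  expect_equal(length(parse_pdb(path)), 2L)
  expect_error(parse_pdb("/no/such/file.pdb"), "input error")
  expect_error(parse_pdb("HEADER  ONLY\nEND"), "empty-structure")
  bad <- sub("   3.800", "   3.8.0", fixture_two_res(), fixed = TRUE)
  expect_error(parse_pdb(bad), "line 3")
})

test_that("only the first MODEL is retained", {
  f <- parse_pdb(fixture_two_models())
  expect_equal(length(f), 2L)
  expect_equal(ca_coords(f)[, 3], c(0, 0))
})

test_that("first-seen altloc conformer wins", {
  f <- parse_pdb(fixture_altloc())
  expect_equal(length(f), 2L)
  expect_equal(unname(ca_coords(f)[1, ]), c(0, 0, 0))
})

test_that("HETATM and hydrogens are excluded from the residue sequence", {
  txt <- paste(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "HA", "GLY", "A", 1, 0.5, 0.5, 0, element = "H"),
    pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(4, "O", "HOH", "A", 101, 9, 9, 9, element = "O",
             record = "HETATM"),
    "END"), collapse = "\n")
  f <- parse_pdb(txt)
  expect_equal(length(f), 2L)
  expect_false(any(f$atoms$element == "H"))
  expect_false(any(f$atoms$res_name == "HOH"))
})

test_that("write_pdb emits one line per atom, TER per chain, END", {
  f <- parse_pdb(fixture_two_res())
  lines <- strsplit(write_pdb(f), "\n")[[1]]
  expect_equal(sum(startsWith(lines, "ATOM")), nrow(f$atoms))
  expect_equal(sum(lines == "TER"), 1L)
  expect_equal(lines[length(lines)], "END")
  tc <- make_two_chain(3)
  expect_equal(sum(strsplit(write_pdb(tc), "\n")[[1]] == "TER"), 2L)
})

test_that("parse/write round-trip preserves structure to 3 decimals", {
  for (f in list(parse_pdb(fixture_two_res()), make_helix(50),
                 make_two_blob(10, 10, 30, seed = 7), make_two_chain(5))) {
    g <- parse_pdb(write_pdb(f))
    expect_equal(length(g), length(f))
    expect_equal(residues(g)$chain, residues(f)$chain)
    expect_equal(residues(g)$author_number, residues(f)$author_number)
    expect_equal(ca_coords(g), ca_coords(f), tolerance = 1e-3)
    h <- parse_pdb(write_pdb(g))
    expect_equal(h$atoms$x, g$atoms$x)
  }
})

test_that("parser agrees with bio3d on a written fixture file", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_helix(20), path)
  ours <- parse_pdb(path)
  ref <- suppressWarnings(bio3d::read.pdb(path))
  ca <- ref$atom[ref$atom$elety == "CA", ]
  expect_equal(unname(ca_coords(ours)),
               unname(as.matrix(ca[, c("x", "y", "z")])),
               tolerance = 1e-6)
  expect_equal(residues(ours)$author_number, ca$resno)
})

test_that("fold_sequence maps standard residues and falls back to X", {
  expect_equal(fold_sequence(parse_pdb(fixture_two_res()), "A"), "GA")
  mse <- paste(c(pdb_line(1, "CA", "MSE", "A", 1, 0, 0, 0),
                 pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0), "END"),
               collapse = "\n")
  expect_equal(fold_sequence(parse_pdb(mse), "A"), "XG")
  expect_error(fold_sequence(parse_pdb(mse), "B"), "key error")
})

test_that("remove_chains drops chains, reindexes, and composes", {
  cx <- parse_pdb(fixture_three_chains())
  expect_equal(cx$chains, c("A", "B", "C"))
  out <- remove_chains(cx, "AB")
  expect_equal(out$chains, "C")
  expect_equal(residues(out)$index, c(0L, 1L))
  expect_identical(remove_chains(cx, ""), cx)
  expect_error(remove_chains(cx, "Z"), "key error.*Z")
  # operator sugar and composition over disjoint sets
  expect_equal((cx - "AB")$chains, "C")
  ab_then_c <- remove_chains(remove_chains(cx, "A"), "B")
  expect_equal(ab_then_c$atoms$x, remove_chains(cx, "AB")$atoms$x)
  expect_equal(ab_then_c$atoms$res_index,
               remove_chains(cx, "AB")$atoms$res_index)
})

test_that("removing chains never reorders surviving residues", {
  cx <- parse_pdb(fixture_three_chains())
  kept <- remove_chains(cx, "B")
  orig <- cx$atoms[cx$atoms$chain %in% c("A", "C"), ]
  expect_equal(kept$atoms$serial, orig$serial)
})

test_that("ca_coords returns exact rows and honors the fallback policy", {
  f <- parse_pdb(fixture_two_res())
  cc <- ca_coords(f)
  expect_equal(dim(cc), c(2L, 3L))
  expect_equal(unname(cc[2, ]), c(3.8, 0, 0))
  no_ca <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                   pdb_line(2, "CB", "ALA", "A", 2, 5, 0, 0), "END"),
                 collapse = "\n")
  g <- parse_pdb(no_ca)
  expect_error(ca_coords(g), "index 1")
  expect_equal(unname(ca_coords(g, fallback = "first_atom")[2, ]), c(5, 0, 0))
})

test_that("distance_matrix: 3-4-5 geometry, symmetry, min_heavy bound", {
  txt <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                 pdb_line(2, "CA", "GLY", "A", 2, 3, 4, 0), "END"),
               collapse = "\n")
  D <- distance_matrix(parse_pdb(txt))
  expect_equal(D[1, 2], 5)
  tc <- make_two_chain(4)
  Dca <- distance_matrix(tc, "ca")
  Dmh <- distance_matrix(tc, "min_heavy")
  expect_true(all(Dmh <= Dca + 1e-12))
  expect_equal(Dmh, t(Dmh))
  expect_equal(diag(Dmh), rep(0, length(tc)))
})

test_that("distance matrices satisfy the triangle inequality", {
  f <- make_two_blob(15, 15, 25, seed = 11)
  for (mode in c("ca", "min_heavy")) {
    D <- distance_matrix(f, mode)
    n <- nrow(D)
    trips <- withr::with_seed(5, {
      t(replicate(120, sample(n, 3)))
    })
    for (r in seq_len(nrow(trips))) {
      i <- trips[r, 1]; j <- trips[r, 2]; k <- trips[r, 3]
      expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-9)
    }
  }
})

test_that("distance_to_chain measures minimum heavy-atom separation", {
  tc <- make_two_chain(6, separation = 4)
  d <- distance_to_chain(tc, "A", "B")
  expect_equal(d, rep(4, 6))
  # rigid +10 A translation of chain B along x increases every entry
  shifted <- tc
  bmask <- shifted$atoms$chain == "B"
  shifted$atoms$x[bmask] <- shifted$atoms$x[bmask] + 100
  d2 <- distance_to_chain(shifted, "A", "B")
  expect_true(all(d2 > d))
  expect_error(distance_to_chain(tc, "A", "A"), "distinct")
  expect_error(distance_to_chain(tc, "A", "Z"), "key error")
})

test_that("interface_residues matches the brute-force atom-pair oracle", {
  tc <- make_two_chain(10, separation = 4)
  expect_equal(interface_residues(tc, "A", "B", cutoff = 5), 0:9)
  expect_equal(length(interface_residues(tc, "A", "B", cutoff = 3)), 0L)
  expect_error(interface_residues(tc, "A", "B", cutoff = -1), "> 0")
  for (cut in c(3, 4.2, 5, 10)) {
    expect_equal(interface_residues(tc, "A", "B", cut),
                 brute_interface(tc, "A", "B", cut))
  }
  blob <- make_two_blob(8, 8, 12, seed = 2)
  blob$atoms$chain[blob$atoms$res_index >= 8] <- "B"
  blob$chains <- c("A", "B")
  for (cut in c(5, 8, 12)) {
    expect_equal(interface_residues(blob, "A", "B", cut),
                 brute_interface(blob, "A", "B", cut))
  }
})

test_that("load_alphafold attaches pLDDT from the B-factor column", {
  txt <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = 80),
                 pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, b = 100),
                 "END"), collapse = "\n")
  af <- load_alphafold(txt)
  expect_s3_class(af, "alphafold")
  expect_equal(af$plddt, c(80, 100))
  expect_equal(mean(af$plddt), 90)
  expect_false(af$plddt_flagged)
  bad <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = 120),
                 pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, b = 90),
                 "END"), collapse = "\n")
  expect_warning(af2 <- load_alphafold(bad), "outside")
  expect_equal(af2$plddt[1], 120)  # kept, flagged
  expect_true(af2$plddt_flagged)
})
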