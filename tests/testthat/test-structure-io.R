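# PDB reading/writing, residue and environment selection, spatial index.

test_that("a minimal hand-written glycine parses to 4 heavy atoms", {
  s <- read_pdb(glycine_pdb_text())
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$atoms), 4L)
  expect_setequal(s$atoms$name, c("N", "CA", "C", "O"))
  expect_false(any(s$atoms$hyd))
})

test_that("malformed coordinate fields are reported with their line number", {
  bad <- sub("1.458", "1.4x8", glycine_pdb_text(), fixed = TRUE)
  expect_error(read_pdb(bad), "line 2")
  expect_error(read_pdb("REMARK nothing here\nEND"), "empty structure")
})

test_that("altlocs resolve to highest occupancy with ties to A", {
  txt <- paste(c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AGLY A   1       1.458   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   1       6.000   0.000   0.000  0.50  0.00           C",
    "END"), collapse = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 5.0)    # occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1.458) # tie -> altloc A
})

test_that("structures round-trip through PDB text within coordinate precision", {
  for (s in list(make_gxg_peptide(), make_symmetric_dimer())) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, path)
    s2 <- read_pdb(path)
    expect_equal(nrow(s2$atoms), nrow(s$atoms))
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(s$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(s2$atoms$name, s$atoms$name)
  }
})

test_that("select_residue returns exactly the requested residue", {
  pep <- make_gxg_peptide()
  mid <- select_residue(pep, site("A", 2))
  expect_true(all(mid$resno == 2L))
  expect_setequal(mid$name, c("N", "CA", "C", "O", "CB"))
  expect_error(select_residue(pep, site("Q", 2)), "site not found")
  expect_error(select_residue(pep, site("A", 99)), "site not found")
})

test_that("insertion codes address the inserted residue, not its neighbour", {
  pep <- make_gxg_peptide()
  ins <- select_residue(pep, site("A", 2))
  ins$ins <- "A"
  ins$resid <- "SER"
  s <- pep
  s$atoms <- rbind(pep$atoms, ins)
  expect_equal(nrow(select_residue(s, site("A", 2, "A"))), 5L)
  expect_equal(unique(select_residue(s, site("A", 2, "A"))$resid), "SER")
  expect_equal(unique(select_residue(s, site("A", 2))$resid), "ALA")
})

test_that("environment excludes the labeled residue, hydrogens, waters and het by default", {
  pep <- make_gxg_peptide()
  extra <- data.frame(
    name = c("O", "H", "FE"), element = c("O", "H", "FE"),
    x = 9, y = c(0, 1, 2), z = 0, resno = c(50L, 51L, 52L), ins = "",
    chain = "A", resid = c("HOH", "GLY", "HEM"),
    het = c(TRUE, FALSE, TRUE), hyd = c(FALSE, TRUE, FALSE))
  s <- pep
  s$atoms <- rbind(pep$atoms, extra)
  env <- environment_for_site(s, site("A", 2))
  expect_false(any(env$resno == 2L))
  expect_false(any(env$hyd))
  expect_false(any(env$resid == "HOH"))
  expect_false(any(env$het))
  env_w <- environment_for_site(s, site("A", 2), include_waters = TRUE,
                                include_hetero = TRUE)
  expect_true(any(env_w$resid == "HOH"))
  expect_true(any(env_w$resid == "HEM"))
})

test_that("environment size matches the counted categories on a fixture", {
  w <- make_wall()
  st <- site("A", 2)
  a <- w$atoms
  own <- sum(a$resno == 2L & a$chain == "A")
  adjacent_bb <- sum(a$chain == "A" & abs(a$resno - 2L) == 1L &
                       a$name %in% c("N", "CA", "C", "O"))
  env <- environment_for_site(w, st)
  expect_equal(nrow(env), nrow(a) - own - adjacent_bb)
  env_raw <- environment_for_site(w, st, exclude_adjacent_backbone = FALSE)
  expect_equal(nrow(env_raw), nrow(a) - own)
})

test_that("multi-MODEL files honour model selection", {
  e <- run_search(make_gxg_peptide(), site("A", 2),
                  search_params("quick", seed = 5))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(e, path)
  s1 <- read_pdb(path, model = 1)
  s2 <- read_pdb(path, model = 2)
  expect_equal(nrow(s1$atoms), 18L)
  expect_false(isTRUE(all.equal(s1$atoms$x, s2$atoms$x)))
  expect_error(read_pdb(path, model = 99), "model")
})

test_that("spatial index agrees with the brute-force scan on random configurations", {
  set.seed(401)
  for (rep in 1:6) {
    n <- sample(c(5L, 100L, 1000L), 1L)
    coords <- matrix(runif(3 * n, 0, 50), ncol = 3)
    idx <- build_spatial_index(coords, cell_size = sample(c(2, 5, 9), 1L))
    for (q in 1:20) {
      point <- runif(3, -5, 55)
      r <- runif(1, 0.5, 8)
      got <- attr(query_radius(idx, point, r), "indices")
      expect_identical(got, brute_radius(coords, point, r))
    }
  }
})

test_that("radius queries use a closed ball and clash tests a strict inequality", {
  coords <- rbind(c(3.39, 0, 0), c(3.4, 0, 0), c(3.41, 0, 0))
  idx <- build_spatial_index(coords, cell_size = 4)
  hits <- attr(query_radius(idx, c(0, 0, 0), 3.4), "indices")
  expect_identical(hits, c(1L, 2L))  # d == r included

  # conformer with a single env atom exactly at the cutoff: not a clash,
  # but a contact
  tpl <- mtssl_template()
  cf <- apply_torsions(tpl, rep(180, 5))
  sg <- cf$coords["SG", ]
  far <- sweep(matrix(sg, 1), 2,
               -(3.4 * c(1, 0, 0)))  # 3.4 A from SG along x
  d <- brute_min_dists(side_chain_xyz(cf), far)
  if (abs(d - 3.4) < 1e-9) {  # guard: SG really is the nearest atom
    expect_equal(clash_count(cf, far, 3.4), 0L)
    expect_equal(contact_count(cf, far, 3.4, 4.5), 1L)
  }
  near <- far
  near[1, 1] <- near[1, 1] - 0.1
  expect_equal(clash_count(cf, near, 3.4), 1L)
})

test_that("empty spatial index returns empty results", {
  idx <- build_spatial_index(matrix(numeric(0), ncol = 3), cell_size = 4)
  expect_length(attr(query_radius(idx, c(0, 0, 0), 5), "indices"), 0L)
})

test_that("ensemble PDB round-trips models, coordinates and flags", {
  pep <- make_gxg_peptide()
  st <- site("A", 2)
  e <- run_search(pep, st, search_params("painstaking", seed = 21))
  e <- flag_snuggly(e, environment_for_site(pep, st))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(e, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), n_conformers(e))
  expect_equal(sum(grepl("^ENDMDL", lines)), n_conformers(e))
  expect_equal(sum(grepl("SNUGGLY 1", lines)),
               sum(vapply(e$conformers, `[[`, logical(1), "snuggly")))
  e2 <- read_ensemble_pdb(path)
  expect_equal(n_conformers(e2), n_conformers(e))
  for (i in c(1L, n_conformers(e))) {
    expect_equal(e2$conformers[[i]]$coords, e$conformers[[i]]$coords,
                 tolerance = 1e-3)
    expect_equal(e2$conformers[[i]]$snuggly, e$conformers[[i]]$snuggly)
    expect_equal(e2$conformers[[i]]$chi, e$conformers[[i]]$chi,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  expect_equal(e2$params$seed, e$params$seed)
  expect_error(write_ensemble_pdb(
    structure(list(conformers = list()), class = "label_ensemble"),
    withr::local_tempfile()), "empty")
})

test_that("a real structure parses with chains, residues and CB atoms", {
  s <- read_pdb(lysozyme_path())
  res <- select_residue(s, site("A", 15))
  expect_true("CB" %in% res$name)
  expect_true(all(c("N", "CA", "C", "O") %in% res$name))
  env <- environment_for_site(s, site("A", 15))
  expect_gt(nrow(env), 900)
  expect_false(any(env$resno == 15L & env$chain == "A"))
})
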