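test_that("chains far apart share no interface residues", {
  m <- read_structure(FAR_CHAINS_PDB, format = "pdb")
  iface <- interface_residues(m, "A", "B")
  expect_equal(nrow(iface$residues_a), 0)
  expect_equal(nrow(iface$residues_b), 0)
  expect_error(interface_residues(m, "A", "Z"), class = "wafer_error_lookup")
})

test_that("interface recovery matches the generator's planted residue set", {
  toy <- toy_fixture()
  iface <- interface_residues(toy$model, "A", "B")
  planted <- toy$manifest$planted$interface
  for (ch in c("A", "B")) {
    got <- if (ch == "A") iface$residues_a else iface$residues_b
    expect_setequal(got$seq_id, planted$seq_id[planted$chain == ch])
  }
  # symmetric under swapping the chains
  iface2 <- interface_residues(toy$model, "B", "A")
  expect_setequal(iface$residues_a$seq_id, iface2$residues_b$seq_id)
  expect_setequal(iface$residues_b$seq_id, iface2$residues_a$seq_id)
})

test_that("the planted wafer motif is recovered exactly at zero noise", {
  toy <- toy_fixture()
  spec <- toy$manifest$spec
  motif <- detect_wafer_motif(toy$model, "A", "B")
  expect_false(is.null(motif$clasp))
  expect_equal(motif$clasp$a$seq_id, spec$clasp_seq)
  expect_equal(motif$clasp$b$seq_id, spec$clasp_seq)
  expect_true(motif$clasp$class != "none")
  expect_equal(motif$clasp$distance, spec$clasp_separation, tolerance = 1e-9)

  # four histidines: His69 + His101 from each chain
  expect_equal(nrow(motif$histidines), 4)
  expect_setequal(
    paste(motif$histidines$chain_id, motif$histidines$seq_id),
    c("A 69", "A 101", "B 69", "B 101"))
  expect_true(motif$complete)

  # two flank pairs, each joining a flank His to the partner clasp His
  expect_length(motif$flanks, 2)
  for (f in motif$flanks) {
    expect_true(f$pair$class != "none" || !is.null(f$polar_evidence))
  }

  # exactly three supporting serines per chain, the planted ones
  for (ch in c("A", "B")) {
    s <- motif$serines[motif$serines$chain_id == ch, ]
    expect_setequal(s$seq_id, spec$ser_seq)
    expect_true(all(s$distance <= wafer_params()$polar_cutoff))
  }
})

test_that("motif detection is symmetric under chain relabeling", {
  toy <- toy_fixture()
  m1 <- detect_wafer_motif(toy$model, "A", "B")
  m2 <- detect_wafer_motif(toy$model, "B", "A")
  expect_equal(m1$clasp$distance, m2$clasp$distance, tolerance = 1e-12)
  expect_equal(m1$clasp$angle, m2$clasp$angle, tolerance = 1e-9)
  expect_setequal(paste(m1$histidines$chain_id, m1$histidines$seq_id),
                  paste(m2$histidines$chain_id, m2$histidines$seq_id))
  expect_setequal(paste(m1$serines$chain_id, m1$serines$seq_id),
                  paste(m2$serines$chain_id, m2$serines$seq_id))
})

test_that("full motif recovery (clasp, flanks, all serines) holds under moderate noise", {
  # sigma = 0.15 A rigid-residue noise: every planted detection margin
  # exceeds 4 standard deviations of the inter-residue distance jitter
  for (seed in 1:50) {
    toy <- make_toy_dimer(dimer_spec(seed = seed, sigma = 0.15))
    spec <- toy$manifest$spec
    motif <- detect_wafer_motif(toy$model, "A", "B")
    expect_false(is.null(motif$clasp), info = sprintf("seed %d", seed))
    expect_equal(c(motif$clasp$a$seq_id, motif$clasp$b$seq_id),
                 rep(spec$clasp_seq, 2))
    expect_equal(nrow(motif$histidines), 4, info = sprintf("seed %d", seed))
    for (ch in c("A", "B")) {
      expect_setequal(motif$serines$seq_id[motif$serines$chain_id == ch],
                      spec$ser_seq)
    }
  }
})

test_that("motif-free dimers yield an empty motif", {
  for (seed in 1:5) {
    toy <- make_toy_dimer(dimer_spec(seed = seed, with_motif = FALSE))
    motif <- detect_wafer_motif(toy$model, "A", "B")
    expect_null(motif$clasp)
    expect_equal(nrow(motif$histidines), 0)
    expect_false(motif$complete)
  }
  # no histidines at all is likewise a valid empty result
  m <- read_structure(FAR_CHAINS_PDB, format = "pdb")
  expect_null(detect_wafer_motif(m, "A", "B")$clasp)
})

test_that("the motif connects the two active sites through planted contacts", {
  toy <- toy_fixture()
  motif <- detect_wafer_motif(toy$model, "A", "B")
  ligs <- extract_ligands(toy$model, "GSH")
  conn <- motif_connects_active_sites(toy$model, motif, ligs)
  expect_true(conn$connected)
  expect_equal(conn$path[1], "GSH[A]")
  expect_equal(conn$path[length(conn$path)], "GSH[B]")
  # interior of the path runs through motif residues only
  interior <- conn$path[-c(1, length(conn$path))]
  motif_labels <- c(
    sprintf("%s:%d", motif$histidines$chain_id, motif$histidines$seq_id),
    sprintf("%s:%d", motif$serines$chain_id, motif$serines$seq_id))
  expect_true(all(interior %in% motif_labels))

  # with a ligand removed there is nothing to connect
  conn1 <- motif_connects_active_sites(toy$model, motif, ligs[1])
  expect_false(conn1$connected)
  expect_length(conn1$path, 0)

  # an empty motif cannot be queried
  empty <- detect_wafer_motif(read_structure(FAR_CHAINS_PDB), "A", "B")
  expect_error(motif_connects_active_sites(toy$model, empty, ligs),
               class = "wafer_error_usage")
})

test_that("motif evidence distances respect the configured cutoffs", {
  toy <- toy_fixture()
  p <- wafer_params()
  motif <- detect_wafer_motif(toy$model, "A", "B", p)
  expect_lte(motif$clasp$distance, p$stack_parallel_dist)
  expect_lte(motif$clasp$angle, p$stack_parallel_angle)
  expect_true(all(motif$serines$distance <= p$polar_cutoff))
  for (f in motif$flanks) {
    if (f$pair$class == "parallel") {
      expect_lte(f$pair$distance, p$stack_parallel_dist)
    }
    if (!is.null(f$polar_evidence)) {
      expect_true(all(f$polar_evidence$distance <= p$flank_atom_cutoff))
    }
  }
})
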