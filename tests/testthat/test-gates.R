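# Gate-layer contact inventories and the closed/open call.

test_that("find_contacts honours the cutoff and is symmetric", {
  s <- plant_site(data.frame(resseq = c(1, 2), resname = "ALA",
                             atom = "CB", element = "C",
                             x = c(0, 3.0), y = 0, z = 0))
  g1 <- residue_group(1); g2 <- residue_group(2)
  expect_equal(nrow(find_contacts(s, g1, g2, cutoff = 4.5)), 1)
  expect_equal(nrow(find_contacts(s, g1, g2, cutoff = 2.5)), 0)
  h12 <- find_contacts(s, g1, g2, 4.5)
  h21 <- find_contacts(s, g2, g1, 4.5)
  expect_equal(h12$distance, h21$distance)
  expect_setequal(paste(h12$res_a, h12$res_b), paste(h21$res_b, h21$res_a))
  expect_equal(h12$distance, 3.0, tolerance = 1e-9)
  expect_error(find_contacts(s, residue_group(99), g2, 4.5), "zero atoms")
})

test_that("hit counts are monotone non-decreasing in the cutoff", {
  set.seed(42)
  n <- 12
  s <- plant_site(data.frame(resseq = seq_len(2 * n),
                             resname = "ALA", atom = "CB", element = "C",
                             x = runif(2 * n, 0, 12), y = runif(2 * n, 0, 12),
                             z = runif(2 * n, 0, 12)))
  gA <- residue_group(1:n); gB <- residue_group(n + 1:n)
  counts <- vapply(seq(2, 12, by = 0.5), function(ct)
    nrow(find_contacts(s, gA, gB, ct)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("find_hbonds detects planted bonds, not distant pairs, only polar types", {
  s <- toy_polar_site()
  hb <- find_hbonds(s, residue_group(17), residue_group(12), 3.5)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.80, tolerance = 1e-9)
  # 4.2 A apart with d_max 3.5: nothing
  far <- plant_site(data.frame(resseq = c(1, 2), resname = c("ALA", "ALA"),
                               atom = c("N", "O"), element = c("N", "O"),
                               x = c(0, 4.2), y = 0, z = 0))
  expect_equal(nrow(find_hbonds(far, residue_group(1), residue_group(2), 3.5)), 0)
  # carbon atoms are never donors/acceptors
  cc <- plant_site(data.frame(resseq = c(1, 2), resname = "ALA",
                              atom = "CB", element = "C",
                              x = c(0, 2.8), y = 0, z = 0))
  expect_error(find_hbonds(cc, residue_group(1), residue_group(2), 3.5),
               "zero polar")
  # planted bidentate salt bridge: both guanidinium N hit carboxylate O
  sb <- find_hbonds(s, residue_group(89), residue_group(95), 3.5)
  expect_setequal(unique(sb$atom_a), c("A/ARG89:NH1", "A/ARG89:NH2"))
  expect_equal(min(sb$distance), 2.70, tolerance = 1e-9)
})

test_that("find_water_bridges finds planted bridges and nothing spurious", {
  s <- toy_polar_site()
  wb <- find_water_bridges(s, residue_group(40), residue_group(50), 3.5)
  expect_equal(nrow(wb), 1)
  expect_equal(wb$water, "A/HOH300")
  expect_equal(wb$kind, "water_bridge")
  expect_equal(wb$distance, 2.80, tolerance = 1e-9)
  # the far group cannot be bridged
  expect_equal(nrow(find_water_bridges(s, residue_group(40), residue_group(60),
                                       3.5)), 0)
  # no waters at all -> empty, not an error
  dry <- plant_site(data.frame(resseq = c(1, 2), resname = "ALA", atom = "O",
                               element = "O", x = c(0, 5.6), y = 0, z = 0))
  expect_equal(nrow(find_water_bridges(dry, residue_group(1), residue_group(2),
                                       3.5)), 0)
})

# toy occluded/inward pair: three "layers", each one residue pair at 3.5 A
# (formed) in the closed toy and pulled to 8 A (broken) in the open toy
toy_gate <- function(open = FALSE) {
  gap <- if (open) 8 else 3.5
  plant_site(data.frame(
    resseq = c(10, 20, 30, 110, 120, 130),
    resname = "ALA", atom = "CB", element = "C",
    x = c(0, 0, 0, gap, gap, gap), y = c(0, 5, 10, 0, 5, 10), z = 0))
}

toy_gate_specs <- function() list(
  contact_spec("C1", residue_group(10), residue_group(110), "hydrophobic"),
  contact_spec("C2", residue_group(20), residue_group(120), "hydrophobic"),
  contact_spec("C3", residue_group(30), residue_group(130), "hydrophobic"))

test_that("gate_state calls closed/open and flags unresolved layers", {
  closed <- gate_state(toy_gate(FALSE), toy_gate_specs())
  expect_equal(closed$state, "closed")
  expect_true(all(closed$layers$formed))
  expect_equal(nrow(closed$layers), 3)

  open <- gate_state(toy_gate(TRUE), toy_gate_specs())
  expect_equal(open$state, "open")
  expect_false(any(open$layers$formed))

  # delete one layer's residues: that layer is unresolved, gate open
  s <- toy_gate(FALSE)
  s <- new_structure(s$atoms[!(s$atoms$resseq %in% c(30, 130)), ], title = "")
  part <- gate_state(s, toy_gate_specs())
  expect_equal(part$state, "open")
  expect_true(part$layers$unresolved[part$layers$layer == "C3"])
  expect_true(all(part$layers$formed[part$layers$layer != "C3"]))

  expect_error(gate_state(toy_gate(FALSE), list()), "no layer specs")
})

test_that("layer-formed threshold counts pairs across a layer's specs", {
  # C1 with two pairs, only one formed: at the default 50% rule it is formed,
  # at a 75% rule it is not
  s <- plant_site(data.frame(
    resseq = c(10, 11, 110), resname = "ALA", atom = "CB", element = "C",
    x = c(0, 50, 3.5), y = 0, z = 0))
  specs <- list(contact_spec("C1", residue_group(c(10, 11)),
                             residue_group(110), "hydrophobic"))
  expect_true(gate_state(s, specs)$layers$formed)
  expect_false(gate_state(s, specs, formed_frac = 0.75)$layers$formed)
})

test_that("default gate-layer table covers the three layers and both kinds", {
  specs <- default_gate_layers()
  layers <- vapply(specs, function(x) x$layer, "")
  expect_setequal(layers, c("C1", "C2", "C3"))
  kinds <- vapply(specs, function(x) x$kind, "")
  expect_true(all(c("hydrophobic", "hbond", "water_bridge") %in% kinds))
  # R378 hydrogen-bonds to the F158/K160 main-chain carbonyls
  r378 <- specs[[which(vapply(specs, function(x)
    378 %in% x$group_C$resseq && x$kind == "hbond", TRUE))[1]]]
  expect_setequal(r378$group_N$resseq, c(158, 160))
})
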