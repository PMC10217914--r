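test_that("anchored candidates end on the diagnostic base", {
  aln <- toy_designable_alignment()
  site <- find_diagnostic_sites(aln, "spA")[1, ]
  fwd <- enumerate_anchored_primers(aln, site, "forward",
                                    design_constraints(tm_window = c(30, 90),
                                                       gc_window = c(0, 1)))
  expect_gt(nrow(fwd), 0)
  expect_true(all(substr(fwd$sequence, fwd$length, fwd$length) ==
                    site$target_base))
  expect_true(all(fwd$anchor_column == site$column))

  rev <- enumerate_anchored_primers(aln, site, "reverse",
                                    design_constraints(tm_window = c(30, 90),
                                                       gc_window = c(0, 1)))
  expect_gt(nrow(rev), 0)
  # reverse candidates are the reverse complement of the template slice
  # ending at the anchor: 3' base complements the target base
  cons <- species_consensus(aln, "spA", "degenerate")
  for (i in seq_len(nrow(rev))) {
    slice <- substr(cons, site$column + 1, site$column + rev$length[i])
    expect_equal(rev$sequence[i], reverse_complement(slice))
  }
  expect_true(all(substr(rev$sequence, rev$length, rev$length) ==
                    reverse_complement(site$target_base)))
})

test_that("candidate enumeration equals a brute-force length filter", {
  aln <- toy_designable_alignment()
  site <- find_diagnostic_sites(aln, "spA")[1, ]
  constraints <- design_constraints(tm_window = c(55, 65))
  got <- enumerate_anchored_primers(aln, site, "reverse", constraints)
  cons <- species_consensus(aln, "spA", "degenerate")
  want <- character(0)
  for (L in 18:25) {
    slice <- substr(cons, site$column + 1, site$column + L)
    if (nchar(slice) < L) next
    p <- reverse_complement(slice)
    tm <- oracle_nn_tm(p)
    gc <- mean(strsplit(p, "")[[1]] %in% c("G", "C"))
    runs <- max(rle(strsplit(p, "")[[1]])$lengths)
    if (tm >= 55 && tm <= 65 && gc >= 0.3 && gc <= 0.7 && runs <= 5) {
      want <- c(want, p)
    }
  }
  expect_setequal(got$sequence, want)
})

test_that("edge-trapped anchors yield an empty list with a reason", {
  aln <- toy_designable_alignment()
  site <- tibble::tibble(column = 2L, target_species = "spA",
                         target_base = substr(aln$sequence[1], 3, 3))
  out <- enumerate_anchored_primers(aln, site, "forward")
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "reason"), "edge|filters")
})

test_that("common-primer ranking prefers low degeneracy", {
  fix <- generate_species_set(fixture_spec(seed = 3))
  commons <- select_common_primer(fix$alignment,
                                  orientation = "forward")
  expect_gt(nrow(commons), 0)
  expect_equal(commons$degeneracy[1], min(commons$degeneracy))
  # a perfectly conserved window ranks with degeneracy 1 and its own
  # consensus sequence appears verbatim in every record
  expect_true(grepl(commons$sequence[1], fix$alignment$sequence[1],
                    fixed = TRUE))
})

test_that("degenerate windows qualify up to the cap, then are dropped", {
  # two Y codes: degeneracy 4 <= 8 qualifies (the shipped common primer
  # pattern); cap 2 rejects it
  aln <- species_alignment(
    id = c("a|1", "b|1"), species = c("a", "b"),
    sequence = c("AAGCCTCCTCATTCGTGCAA", "AAGCCTTCTTATTCGTGCAA"))
  w <- conserved_windows(aln, c(18, 18), max_degeneracy = 8)
  expect_true(any(w$degeneracy == 4))
  expect_true("AAGCCTYCTYATTCGTGC" %in% w$consensus)
  w2 <- conserved_windows(aln, c(18, 18), max_degeneracy = 2)
  expect_false(any(w2$degeneracy > 2))
  commons <- select_common_primer(
    aln, orientation = "forward",
    constraints = design_constraints(tm_window = c(30, 90),
                                     gc_window = c(0, 1)))
  expect_true("AAGCCTYCTYATTCGTGC" %in% commons$sequence)
})

test_that("gel-mode panels honor the band-spacing ladder", {
  fix <- generate_species_set(fixture_spec(seed = 11))
  panel <- design_panel(fix$alignment, "gel")
  expect_true(panel_ok(panel))
  lens <- panel$expected$length
  expect_length(lens, 4)
  gaps <- abs(outer(lens, lens, "-"))[upper.tri(diag(4))]
  expect_true(all(gaps >= 40))
  expect_true(all(lens >= 80 & lens <= 500))
})

test_that("melt-mode panels enforce the product-Tm separation floor", {
  fix <- generate_species_set(fixture_spec(seed = 2))
  panel <- design_panel(fix$alignment, "melt")
  expect_true(panel_ok(panel))
  tms <- panel$expected$product_tm
  dtm <- abs(outer(tms, tms, "-"))[upper.tri(diag(length(tms)))]
  expect_true(all(dtm >= 1.0))
  lens <- panel$expected$length
  gaps <- abs(outer(lens, lens, "-"))[upper.tri(diag(length(lens)))]
  expect_true(all(gaps >= 40))
})

test_that("assembly rejects near-Tm pairs and picks a compliant set", {
  # hand-built candidate tables: best-spaced pair differs by 0.4 C and
  # must be rejected in melt mode in favor of a >= 1.0 C assignment
  common <- tibble::tibble(
    name = "common", sequence = "ACGTACGTACGTACGTACGT",
    species = "universal", orientation = "forward",
    anchor_column = NA_integer_, tm = 60, gc = 0.5, length = 20,
    degeneracy = 1)
  mk <- function(nm, sp, product_len, product_tm) tibble::tibble(
    name = nm, sequence = "TTTTACGTACGTACGTACGA", species = sp,
    orientation = "reverse", anchor_column = NA_integer_, tm = 58,
    gc = 0.45, length = 20, degeneracy = 1,
    exp_length = product_len, exp_tm = product_tm,
    exp_sequence = strrep("A", product_len))
  tabs <- list(s1 = rbind(mk("s1_a", "s1", 150, 80.0),
                          mk("s1_b", "s1", 300, 78.0)),
               s2 = rbind(mk("s2_a", "s2", 450, 80.4),
                          mk("s2_b", "s2", 460, 81.5)))
  sel_gel <- mulliplex:::search_assignment(tabs, "gel",
                                           design_constraints())
  # gel mode maximizes the minimum gap: 150/460 beats 150/450 etc.
  expect_equal(sel_gel, c(1L, 2L))
  sel_melt <- mulliplex:::search_assignment(tabs, "melt",
                                            design_constraints())
  lens <- c(tabs$s1$exp_tm[sel_melt[1]], tabs$s2$exp_tm[sel_melt[2]])
  expect_gte(abs(diff(lens)), 1.0)
})

test_that("panel search equals an exhaustive enumerator on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    spec <- fixture_spec(n_species = 3, haplotypes_per_species = 4,
                         barcode_length = 420, n_diagnostic_sites = 3,
                         intraspecific_mut_rate = 0, seed = 100 + rep)
    fix <- generate_species_set(spec)
    aln <- fix$alignment
    sites <- find_all_diagnostic_sites(aln)
    commons <- select_common_primer(aln, orientation = "forward")
    if (!nrow(commons)) next
    specifics <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
      enumerate_anchored_primers(aln, sites[i, ], "reverse")))
    templates <- tibble::tibble(
      species = species_levels(aln),
      sequence = vapply(species_levels(aln), function(sp)
        species_consensus(aln, sp, "majority"), ""))
    got <- assemble_panel(commons, specifics, templates, "gel",
                          max_common_tried = 1)
    # independent enumerator over the same candidate products
    tabs <- lapply(split(specifics, specifics$species), function(cands)
      mulliplex:::expected_products_for(commons[1, ], cands,
                                        templates$sequence[
                                          templates$species ==
                                            cands$species[1]],
                                        thermo_config(),
                                        design_constraints()))
    tabs <- Filter(function(t) !is.null(t) && nrow(t) > 0, tabs)
    oracle <- if (length(tabs) == 3)
      oracle_best_panel(tabs, "gel", 40, 1.0) else list(sel = NULL)
    if (is.null(oracle$sel)) {
      expect_false(panel_ok(got))
    } else {
      expect_true(panel_ok(got))
      lens <- sort(got$expected$length)
      want <- sort(vapply(seq_along(tabs), function(i)
        tabs[[i]]$exp_length[oracle$sel[i]], 0L))
      dl <- function(v) min(abs(outer(v, v, "-"))[upper.tri(diag(3))])
      expect_equal(dl(as.numeric(lens)), dl(as.numeric(want)))
    }
  }
})

test_that("accepted panels re-validate on their own consensus templates", {
  fix <- generate_species_set(fixture_spec(seed = 8))
  panel <- design_panel(fix$alignment, "gel")
  expect_true(panel_ok(panel))
  for (sp in panel$specifics$species) {
    tmpl <- gsub("-", "", species_consensus(fix$alignment, sp, "majority"))
    amps <- simulate_multiplex(panel, tibble::tibble(id = sp,
                                                     sequence = tmpl))
    expect_equal(nrow(amps), 1L)
    expect_equal(amps$length,
                 panel$expected$length[panel$expected$species == sp])
    expect_equal(amps$assigned_species, sp)
  }
})

test_that("panel reports are byte-identical across repeated runs", {
  fix <- generate_species_set(fixture_spec(seed = 4))
  p1 <- design_panel(fix$alignment, "gel")
  p2 <- design_panel(fix$alignment, "gel")
  expect_identical(tidy(p1), tidy(p2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(p1, f1)
  write_panel_tsv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("assembly failures carry the responsible species or constraint", {
  fix <- generate_species_set(fixture_spec(seed = 11))
  aln <- fix$alignment
  commons <- select_common_primer(aln, orientation = "forward")
  sites <- find_all_diagnostic_sites(aln)
  specifics <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    enumerate_anchored_primers(aln, sites[i, ], "reverse")))
  templates <- tibble::tibble(
    species = species_levels(aln),
    sequence = vapply(species_levels(aln), function(sp)
      species_consensus(aln, sp, "majority"), ""))
  res <- assemble_panel(commons,
                        specifics[specifics$species != "species_A", ],
                        templates, "gel")
  expect_false(panel_ok(res))
  expect_match(res$reason, "species_A")

  squeezed <- design_constraints(min_band_spacing = 500L)
  res2 <- assemble_panel(commons, specifics, templates, "gel",
                         constraints = squeezed)
  expect_false(panel_ok(res2))
  expect_match(res2$reason, "no feasible")
})
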