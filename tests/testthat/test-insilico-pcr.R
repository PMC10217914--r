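test_that("an exact substring yields exactly one forward site", {
  template <- paste0(strrep("A", 30), "CCGTTAGGCATCAGTT", strrep("G", 30))
  sites <- find_binding_sites("CCGTTAGGCATCAGTT", template)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 30L)
  expect_equal(sites$end, 46L)
  expect_equal(sites$mismatches, 0L)
})

test_that("a 3'-terminal mismatch kills binding despite internal tolerance", {
  set.seed(37)
  template <- random_dna(120)
  # primer equal to a template slice but with the 3' base flipped
  slice <- substr(template, 41, 60)
  bad3 <- paste0(substr(slice, 1, 19),
                 setdiff(c("A", "C", "G", "T"),
                         c(substr(slice, 20, 20),
                           # avoid accidental matches elsewhere: flip to a
                           # base absent at every candidate 3' position
                           unique(strsplit(template, "")[[1]])))[1])
  # construct instead on a homogeneous template where the anchor base is
  # simply absent
  template2 <- strrep("AC", 60)
  primer <- paste0(substr(template2, 1, 19), "G") # G never at 3' match
  sites <- find_binding_sites(primer, template2)
  expect_equal(nrow(sites), 0L)
})

test_that("internal mismatches are tolerated up to the model cap", {
  template <- paste0(strrep("T", 20), "ACGGACTAGCATGCCATGCA", strrep("T", 20))
  primer0 <- "ACGGACTAGCATGCCATGCA"
  mutate_at <- function(p, i) {
    ch <- strsplit(p, "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  p2 <- mutate_at(mutate_at(primer0, 3), 9)
  expect_equal(nrow(find_binding_sites(p2, template)), 1L)
  expect_equal(find_binding_sites(p2, template)$mismatches, 2L)
  p3 <- mutate_at(p2, 12)
  expect_equal(nrow(find_binding_sites(p3, template)), 0L)
  # the cap is configurable
  loose <- mismatch_model(max_internal_mismatches = 3)
  expect_equal(nrow(find_binding_sites(p3, template, model = loose)), 1L)
})

test_that("binding scan equals the brute-force comparator on random pairs", {
  set.seed(43)
  for (i in 1:500) {
    template <- random_dna(sample(60:140, 1))
    if (i %% 3 == 0) {
      # plant a (possibly degenerate) near-copy of a template slice
      s <- sample(20:60, 1)
      primer <- substr(template, s, s + sample(10:14, 1))
      ch <- strsplit(primer, "")[[1]]
      j <- sample(seq_along(ch), 1)
      ch[j] <- sample(c("A", "C", "G", "T", "Y", "R", "N"), 1)
      primer <- paste(ch, collapse = "")
    } else if (i %% 3 == 1) {
      primer <- random_iupac(sample(10:14, 1))
    } else {
      primer <- reverse_complement(substr(template, 10,
                                          10 + sample(10:14, 1)))
    }
    got <- find_binding_sites(primer, template)
    want <- oracle_binding_sites(primer, template)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mism)
    }
  }
})

test_that("template N matches only under the permissive flag", {
  template <- paste0(strrep("T", 10), "ACGGACTAGCATGCNATGCA", strrep("T", 10))
  primer <- "ACGGACTAGCATGCCATGCA"
  strict <- find_binding_sites(primer, template)
  # N counts as a mismatch (internal position 15): still within cap
  expect_equal(strict$mismatches, 1L)
  perm <- find_binding_sites(primer, template, permissive_n = TRUE)
  expect_equal(perm$mismatches, 0L)
})

test_that("strand symmetry: reverse-complementing the template mirrors sites", {
  set.seed(47)
  for (i in 1:20) {
    template <- random_dna(100)
    primer <- substr(template, 30, 49)
    a <- find_binding_sites(primer, template)
    b <- find_binding_sites(primer, reverse_complement(template))
    expect_equal(nrow(a), nrow(b))
    # a + site at [s, e) maps to a - site at [n - e, n - s)
    expect_setequal(100L - b$end, a$start)
    expect_setequal(ifelse(b$strand == "+", "-", "+"), a$strand)
  }
})

test_that("multiplex simulation on shipped panel references is exact", {
  panels <- mullidae_panels()
  refs <- synthetic_panel_references(panels$co1_multiplex, seed = 7)
  amps <- simulate_multiplex(panels$co1_multiplex,
                             tibble::tibble(id = refs$species,
                                            sequence = refs$sequence))
  expect_equal(nrow(amps), 4L)
  expect_setequal(amps$length, c(193L, 244L, 351L, 436L))
  expect_equal(amps$assigned_species, amps$template_id)
  # product footprints: fwd primer expansion at the 5' end, reverse
  # complement of the specific at the 3' end
  for (i in seq_len(nrow(amps))) {
    spec <- panels$co1_multiplex$specifics
    spec <- spec[spec$species == amps$assigned_species[i], ]
    tail_opts <- vapply(expand_degenerate(spec$sequence),
                        reverse_complement, "")
    expect_true(any(endsWith(amps$sequence[i], tail_opts)))
    head_opts <- expand_degenerate(panels$co1_multiplex$common$sequence)
    expect_true(any(startsWith(amps$sequence[i], head_opts)))
  }
})

test_that("templates without anchor bases yield no products", {
  panels <- mullidae_panels()
  set.seed(53)
  outsider <- random_dna(700) # a non-target fish: no primer sites
  amps <- simulate_multiplex(panels$co1_multiplex,
                             c(trachurus_like = outsider))
  expect_equal(nrow(amps), 0L)
})

test_that("multiplex products equal paired brute-force binding sites", {
  fix <- generate_species_set(fixture_spec(seed = 11))
  panel <- design_panel(fix$alignment, "gel")
  expect_true(panel_ok(panel))
  tmpl <- gsub("-", "", fix$alignment$sequence[1])
  amps <- simulate_multiplex(panel, c(h1 = tmpl))
  prim <- panel_primers(panel)
  sites <- do.call(rbind, lapply(seq_len(nrow(prim)), function(p) {
    df <- oracle_binding_sites(prim$sequence[p], tmpl)
    if (nrow(df)) df$primer <- prim$name[p]
    df
  }))
  fwd <- sites[sites$strand == "+", , drop = FALSE]
  rev <- sites[sites$strand == "-", , drop = FALSE]
  pairs <- 0L
  lens <- integer(0)
  for (a in seq_len(nrow(fwd))) for (b in seq_len(nrow(rev))) {
    pl_f <- nchar(prim$sequence[prim$name == fwd$primer[a]])
    pl_r <- nchar(prim$sequence[prim$name == rev$primer[b]])
    if (rev$start[b] < fwd$start[a] + pl_f) next
    len <- rev$start[b] + pl_r - fwd$start[a]
    if (len > 2000) next
    pairs <- pairs + 1L
    lens <- c(lens, len)
  }
  expect_equal(nrow(amps), pairs)
  expect_setequal(amps$length, lens)
})

test_that("cross-reactivity on a designed panel is identity-patterned", {
  fix <- generate_species_set(fixture_spec(seed = 11))
  panel <- design_panel(fix$alignment, "gel")
  templates <- tibble::tibble(
    species = species_levels(fix$alignment),
    sequence = vapply(species_levels(fix$alignment), function(sp)
      gsub("-", "", species_consensus(fix$alignment, sp, "majority")), ""))
  xr <- cross_reactivity(panel, templates)
  expect_true(xr$pass)
  m <- as.matrix(xr)
  expect_equal(unname(diag(m)), rep(1L, 4))
  expect_equal(sum(m) - sum(diag(m)), 0L)
  # row sums match a full multiplex restricted to that primer pair
  counts <- tidy(xr)
  for (sp in panel$specifics$species) {
    sub <- mulliplex:::subset_panel(panel, sp)
    total <- sum(vapply(seq_len(nrow(templates)), function(i)
      nrow(simulate_multiplex(sub,
                              tibble::tibble(id = templates$species[i],
                                             sequence =
                                               templates$sequence[i]))), 0L))
    expect_equal(sum(counts$n_products[counts$primer_set == sp]), total)
  }
  expect_error(cross_reactivity(panel, templates[-1, ]),
               "missing template")
})

test_that("a shared anchor base breaks specificity and is reported", {
  fix <- generate_species_set(fixture_spec(seed = 11))
  panel <- design_panel(fix$alignment, "gel")
  templates <- tibble::tibble(
    species = species_levels(fix$alignment),
    sequence = vapply(species_levels(fix$alignment), function(sp)
      gsub("-", "", species_consensus(fix$alignment, sp, "majority")), ""))
  # graft species_A's specific-primer site into species_B's template
  spec_a <- panel$specifics[panel$specifics$species == "species_A", ]
  site_a <- find_binding_sites(spec_a, templates$sequence[1])
  hit <- site_a[site_a$strand == "-", ][1, ]
  seqs <- templates$sequence
  substr(seqs[2], hit$start + 1, hit$end) <-
    substr(seqs[1], hit$start + 1, hit$end)
  xr <- cross_reactivity(panel, tibble::tibble(species = templates$species,
                                               sequence = seqs))
  expect_false(xr$pass)
  m <- as.matrix(xr)
  expect_gte(m["species_A", "species_B"], 1L)
})

test_that("3'-dimer runs match the exhaustive offset oracle", {
  expect_equal(predict_dimers(c(a = "ACGTACAAAA",
                                b = "ACGTACTTTT"))$max_3prime_complement_run,
               c(oracle_dimer_run("ACGTACAAAA", "ACGTACAAAA"),
                 oracle_dimer_run("ACGTACAAAA", "ACGTACTTTT"),
                 oracle_dimer_run("ACGTACTTTT", "ACGTACTTTT")))
  d <- predict_dimers(c(x = "GGGGGAAAA", y = "CCCCCTTTT"), threshold = 4)
  row_xy <- d[d$primer_a == "x" & d$primer_b == "y", ]
  expect_true(row_xy$flagged)
  expect_gte(row_xy$max_3prime_complement_run, 4)
  d0 <- predict_dimers(c(x = "CCCCAAAA", y = "CCCCAAAA"), threshold = 4)
  expect_false(any(d0$flagged[d0$primer_a == "x" & d0$primer_b == "y"]))
  set.seed(59)
  for (i in 1:100) {
    a <- random_dna(sample(8:20, 1))
    b <- random_dna(sample(8:20, 1))
    got <- predict_dimers(c(a = a, b = b))
    expect_equal(got$max_3prime_complement_run[got$primer_a == "a" &
                                                 got$primer_b == "b"],
                 oracle_dimer_run(a, b))
  }
})
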