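# In-silico PCR engine. Binding follows a 3'-strict mismatch model: the
# 3'-terminal bases must match exactly (this is the mechanism that makes a
# SNP-anchored primer species-specific) while a small number of internal
# mismatches is tolerated. A primer code matches a template base iff the
# base lies in the code's IUPAC expansion; template N matches nothing
# unless the permissive-N flag is set; gaps never match.

#' Binding mismatch model
#'
#' @param three_prime_exact_len Number of 3'-terminal bases that must match
#'   exactly (default 3).
#' @param max_internal_mismatches Mismatches tolerated 5' of the exact
#'   region (default 2).
#' @return A `mismatch_model` list.
#' @export
mismatch_model <- function(three_prime_exact_len = 3L,
                           max_internal_mismatches = 2L) {
  structure(list(three_prime_exact_len = as.integer(three_prime_exact_len),
                 max_internal_mismatches = as.integer(max_internal_mismatches)),
            class = "mismatch_model")
}

# logical match matrix rows for a primer char vector against template chars
# at a set of alignment offsets; template_chars is the full template split.
scan_one_strand <- function(primer_chars, template_chars, exact_idx,
                            max_internal, permissive_n) {
  L <- length(primer_chars)
  n <- length(template_chars)
  if (L > n) return(list(starts = integer(0), mismatches = integer(0)))
  starts <- seq_len(n - L + 1L)
  match_mat <- IUPAC_MATCH
  if (permissive_n) match_mat[, "N"] <- TRUE
  ok <- matrix(TRUE, length(starts), L)
  for (j in seq_len(L)) {
    tb <- template_chars[starts + j - 1L]
    ok[, j] <- match_mat[primer_chars[j], tb]
  }
  internal_idx <- setdiff(seq_len(L), exact_idx)
  exact_ok <- if (length(exact_idx) == 1L) ok[, exact_idx] else
    rowSums(ok[, exact_idx, drop = FALSE]) == length(exact_idx)
  mism <- rowSums(!ok[, internal_idx, drop = FALSE])
  keep <- exact_ok & mism <= max_internal
  list(starts = starts[keep], mismatches = mism[keep])
}

#' Find primer binding sites on a template
#'
#' Scans both strands. A site on strand `+` is a forward-acting site (the
#' primer matches the top strand and extends rightward); a site on strand
#' `-` is reverse-acting (the primer's reverse complement matches the top
#' strand; the primer's 3' end sits at the footprint's left edge and
#' extension runs leftward). Coordinates are 0-based half-open on the
#' template's top strand.
#'
#' @param primer Primer sequence (IUPAC) or a one-row candidate tibble with
#'   columns name and sequence.
#' @param template Ungapped template sequence.
#' @param model A [mismatch_model()].
#' @param permissive_n Should template N match any primer base?
#' @param template_id Optional template label carried into the output.
#' @return Tibble: primer, template_id, strand, start, end, mismatches,
#'   three_prime_exact, sorted by coordinate.
#' @export
find_binding_sites <- function(primer, template, model = mismatch_model(),
                               permissive_n = FALSE, template_id = NA_character_) {
  if (is.data.frame(primer)) {
    pname <- primer$name[1]
    pseq <- primer$sequence[1]
  } else {
    pname <- NA_character_
    pseq <- primer
  }
  pseq <- normalize_seq(pseq)
  assert_iupac(pseq, what = "primer")
  template <- normalize_seq(template)
  if (grepl("-", template, fixed = TRUE)) {
    abort("template contains gaps; ungap it before scanning")
  }
  tch <- seq_chars(template)
  badt <- which(!tch %in% c("A", "C", "G", "T", "N"))
  if (length(badt)) {
    abort(sprintf(
      "template position %d is '%s'; templates must be concrete A/C/G/T/N",
      badt[1], tch[badt[1]]))
  }
  pch <- seq_chars(pseq)
  L <- length(pch)
  k <- min(model$three_prime_exact_len, L)
  empty <- tibble(primer = character(), template_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  mismatches = integer(), three_prime_exact = logical())
  if (L > length(tch)) return(empty)

  # forward-acting: primer as-is vs top strand; 3' end = last k positions
  fwd <- scan_one_strand(pch, tch, exact_idx = (L - k + 1L):L,
                         max_internal = model$max_internal_mismatches,
                         permissive_n = permissive_n)
  # reverse-acting: reverse complement vs top strand; primer 3' terminal
  # bases land on the first k footprint positions
  rch <- seq_chars(reverse_complement(pseq))
  rev <- scan_one_strand(rch, tch, exact_idx = seq_len(k),
                         max_internal = model$max_internal_mismatches,
                         permissive_n = permissive_n)

  out <- bind_rows(
    tibble(primer = pname, template_id = template_id, strand = "+",
           start = fwd$starts - 1L, end = fwd$starts - 1L + L,
           mismatches = as.integer(fwd$mismatches), three_prime_exact = TRUE),
    tibble(primer = pname, template_id = template_id, strand = "-",
           start = rev$starts - 1L, end = rev$starts - 1L + L,
           mismatches = as.integer(rev$mismatches), three_prime_exact = TRUE))
  arrange(out, .data$start, .data$strand)
}

# Coerce template inputs (tibble id/species/sequence, named character
# vector, or species_alignment) to a tidy template tibble.
as_templates <- function(templates) {
  if (inherits(templates, "species_alignment")) {
    return(tibble(id = templates$id, species = templates$species,
                  sequence = gsub("-", "", templates$sequence, fixed = TRUE)))
  }
  if (is.character(templates)) {
    ids <- names(templates) %||% paste0("template", seq_along(templates))
    return(tibble(id = ids, species = NA_character_,
                  sequence = unname(templates)))
  }
  tb <- as_tibble(templates)
  if (!"species" %in% names(tb)) tb$species <- NA_character_
  tb[, c("id", "species", "sequence")]
}

#' Simulate a multiplex PCR
#'
#' Runs every panel primer against every template, pairs each
#' forward-acting site with each downstream reverse-acting site within
#' `max_amplicon`, and emits the predicted products. A product's
#' `assigned_species` is the species of the specific primer(s) involved
#' (`NA` if two specifics of different species pair, which a one-common
#' panel cannot produce on clean templates). No products means no
#' amplification -- the negative-control outcome.
#'
#' @param panel A `primer_panel`.
#' @param templates Templates: tibble with columns id, sequence (optionally
#'   species), a named character vector, or a `species_alignment`.
#' @param model A [mismatch_model()].
#' @param max_amplicon Longest product reported when scanning arbitrary
#'   templates (default 2000 nt).
#' @param permissive_n Template-N handling, see [find_binding_sites()].
#' @return Tibble of `AmpliconPrediction`s: template_id, fwd_primer,
#'   rev_primer, start, end, length, sequence, product_tm,
#'   assigned_species.
#' @export
simulate_multiplex <- function(panel, templates, model = mismatch_model(),
                               max_amplicon = 2000L, permissive_n = FALSE) {
  stopifnot(inherits(panel, "primer_panel"))
  templates <- as_templates(templates)
  primers <- panel_primers(panel)
  out <- vector("list", 0L)
  for (i in seq_len(nrow(templates))) {
    tid <- templates$id[i]
    seqi <- normalize_seq(templates$sequence[i])
    sites <- purrr::map_dfr(seq_len(nrow(primers)), function(p) {
      find_binding_sites(primers[p, ], seqi, model = model,
                         permissive_n = permissive_n, template_id = tid)
    })
    if (!nrow(sites)) next
    fwd <- sites[sites$strand == "+", , drop = FALSE]
    rev <- sites[sites$strand == "-", , drop = FALSE]
    if (!nrow(fwd) || !nrow(rev)) next
    for (a in seq_len(nrow(fwd))) for (b in seq_len(nrow(rev))) {
      # converging: reverse footprint fully downstream of forward footprint
      if (rev$start[b] < fwd$end[a]) next
      len <- rev$end[b] - fwd$start[a]
      if (len > max_amplicon) next
      prod_seq <- substr(seqi, fwd$start[a] + 1L, rev$end[b])
      sp_f <- primers$species[primers$name == fwd$primer[a]][1]
      sp_r <- primers$species[primers$name == rev$primer[b]][1]
      sp <- setdiff(unique(c(sp_f, sp_r)), "universal")
      assigned <- if (length(sp) == 1L) sp else NA_character_
      out[[length(out) + 1L]] <- tibble(
        template_id = tid, fwd_primer = fwd$primer[a],
        rev_primer = rev$primer[b], start = fwd$start[a], end = rev$end[b],
        length = len, sequence = prod_seq,
        product_tm = if (len >= 50L)
          product_tm(prod_seq, cfg = panel$thermo) else NA_real_,
        assigned_species = assigned)
    }
  }
  if (!length(out)) {
    return(tibble(template_id = character(), fwd_primer = character(),
                  rev_primer = character(), start = integer(),
                  end = integer(), length = integer(), sequence = character(),
                  product_tm = double(), assigned_species = character()))
  }
  bind_rows(out) |>
    arrange(.data$template_id, .data$start, .data$end)
}

#' Cross-reactivity matrix of a panel
#'
#' For every specific primer, runs (common + that specific) alone against
#' each species' template. A specific panel amplifies exactly once from its
#' own template and never from any other: the matrix must be
#' identity-patterned (diagonal 1, off-diagonal 0) to pass.
#'
#' @param panel A `primer_panel`.
#' @param templates Tibble with columns species, sequence: exactly one
#'   template per panel species.
#' @param model A [mismatch_model()].
#' @param max_amplicon Product length cap.
#' @return A `cross_reactivity` object; `tidy()` gives the long
#'   counts table, `glance()` the pass flag.
#' @export
cross_reactivity <- function(panel, templates, model = mismatch_model(),
                             max_amplicon = 2000L) {
  stopifnot(inherits(panel, "primer_panel"))
  panel_species <- sort(panel$specifics$species)
  templates <- as_tibble(templates)
  missing <- setdiff(panel_species, templates$species)
  if (length(missing)) {
    abort(sprintf("missing template for panel species: %s",
                  paste(missing, collapse = ", ")))
  }
  templates <- templates[match(panel_species, templates$species), ]
  counts <- purrr::map_dfr(panel_species, function(sp) {
    sub <- subset_panel(panel, sp)
    purrr::map_dfr(seq_len(nrow(templates)), function(i) {
      amps <- simulate_multiplex(
        sub, tibble(id = templates$species[i],
                    sequence = templates$sequence[i]),
        model = model, max_amplicon = max_amplicon)
      tibble(primer_set = sp, template_species = templates$species[i],
             n_products = nrow(amps),
             lengths = paste(amps$length, collapse = ","))
    })
  })
  diag_ok <- all(counts$n_products[counts$primer_set ==
                                     counts$template_species] == 1L)
  off_ok <- all(counts$n_products[counts$primer_set !=
                                    counts$template_species] == 0L)
  structure(list(counts = counts, pass = diag_ok && off_ok,
                 species = panel_species),
            class = "cross_reactivity")
}

#' @export
print.cross_reactivity <- function(x, ...) {
  cat(sprintf("<cross_reactivity> %d primer sets x %d templates: %s\n",
              length(x$species), length(x$species),
              if (x$pass) "PASS (identity-patterned)" else "FAIL"))
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.cross_reactivity <- function(x, ...) {
  m <- matrix(0L, length(x$species), length(x$species),
              dimnames = list(primer_set = x$species,
                              template = x$species))
  for (i in seq_len(nrow(x$counts))) {
    m[x$counts$primer_set[i], x$counts$template_species[i]] <-
      x$counts$n_products[i]
  }
  m
}

#' @export
tidy.cross_reactivity <- function(x, ...) x$counts

#' @export
glance.cross_reactivity <- function(x, ...) {
  tibble(pass = x$pass, n_sets = length(x$species))
}

# longest complementary run in any 3'-anchored antiparallel overlap of the
# 3' ends of primers a and b
dimer_run_3prime <- function(a, b) {
  ach <- seq_chars(normalize_seq(a))
  bch <- seq_chars(normalize_seq(b))
  La <- length(ach)
  Lb <- length(bch)
  can_pair <- function(x, y) {
    any(IUPAC_SETS[[x]] %in% IUPAC_COMPLEMENT[IUPAC_SETS[[y]]])
  }
  best <- 0L
  for (k in seq_len(min(La, Lb))) {
    # overlap of length k anchored at both 3' ends:
    # a[La-k+i] pairs with b[Lb-i+1], i = 1..k
    run <- 0L
    for (i in seq_len(k)) {
      if (can_pair(ach[La - k + i], bch[Lb - i + 1L])) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
    }
  }
  best
}

#' Screen a panel for 3'-anchored primer dimers
#'
#' For every unordered primer pair (self-pairs included) computes the
#' longest complementary run across all 3'-anchored antiparallel overlaps
#' of the two 3' ends, and flags runs at or above `threshold` (dimers show
#' up in melt curves as a low-Tm artifact peak).
#'
#' @param panel A `primer_panel`, or a character vector of primer
#'   sequences (optionally named).
#' @param threshold Complementary-run length that triggers a flag
#'   (default 4).
#' @return Tibble: primer_a, primer_b, max_3prime_complement_run, flagged.
#' @export
predict_dimers <- function(panel, threshold = 4L) {
  if (inherits(panel, "primer_panel")) {
    p <- panel_primers(panel)
    seqs <- setNames(p$sequence, p$name)
  } else {
    seqs <- panel
    if (is.null(names(seqs))) names(seqs) <- paste0("primer", seq_along(seqs))
  }
  if (length(seqs) < 1L) abort("need at least one primer")
  pairs <- expand_grid(a = names(seqs), b = names(seqs)) |>
    filter(.data$a <= .data$b)
  pairs |>
    mutate(max_3prime_complement_run = purrr::map2_int(
      .data$a, .data$b, function(x, y)
        as.integer(dimer_run_3prime(seqs[[x]], seqs[[y]])))) |>
    mutate(flagged = .data$max_3prime_complement_run >= threshold) |>
    rename(primer_a = "a", primer_b = "b")
}
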