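# Panel design: enumerate SNP-anchored species-specific candidates, pick a
# consensus common primer from conserved windows, and search one-per-species
# assignments satisfying the readout constraints (size ladder for gels,
# size ladder + product-Tm separation for melt-curve qPCR).

#' Design constraints for panel assembly
#'
#' Defaults: primer length 18-25 nt, primer Tm window 50-65 deg C, GC
#' 30-70%, homopolymer runs capped at 5, common-primer degeneracy capped at
#' 8 and specific-primer degeneracy at 4, band spacing at least 40 nt
#' (resolvable on a 2% agarose gel), product-Tm separation at least
#' 1.0 deg C in melt mode, amplicons between 80 and 500 nt.
#'
#' @param primer_len `c(min, max)` primer length in nt.
#' @param tm_window `c(min, max)` primer Tm window in deg C.
#' @param gc_window `c(min, max)` primer GC fraction.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param max_common_degeneracy Expansion cap for the common primer.
#' @param max_specific_degeneracy Expansion cap for specific primers
#'   (intraspecific Y/R in the consensus is tolerated up to this).
#' @param min_band_spacing Minimum pairwise amplicon length difference, nt.
#' @param min_tm_separation Minimum pairwise product-Tm difference in melt
#'   mode, deg C.
#' @param min_amplicon,max_amplicon Expected amplicon length bounds, nt.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(primer_len = c(18L, 25L),
                               tm_window = c(50, 65),
                               gc_window = c(0.30, 0.70),
                               max_homopolymer = 5L,
                               max_common_degeneracy = 8L,
                               max_specific_degeneracy = 4L,
                               min_band_spacing = 40L,
                               min_tm_separation = 1.0,
                               max_amplicon = 500L,
                               min_amplicon = 80L) {
  stopifnot(primer_len[1] < primer_len[2], tm_window[1] < tm_window[2],
            gc_window[1] < gc_window[2], min_amplicon < max_amplicon,
            min_tm_separation > 0)
  structure(list(primer_len = as.integer(primer_len),
                 tm_window = tm_window, gc_window = gc_window,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_common_degeneracy = max_common_degeneracy,
                 max_specific_degeneracy = max_specific_degeneracy,
                 min_band_spacing = min_band_spacing,
                 min_tm_separation = min_tm_separation,
                 max_amplicon = as.integer(max_amplicon),
                 min_amplicon = as.integer(min_amplicon)),
            class = "design_constraints")
}

empty_candidates <- function(reason = NULL) {
  out <- tibble(name = character(), sequence = character(),
                species = character(), orientation = character(),
                anchor_column = integer(), tm = double(), gc = double(),
                length = integer(), degeneracy = double())
  attr(out, "reason") <- reason
  out
}

primer_filters_ok <- function(seq, tm, constraints) {
  gc <- gc_content(seq)
  tm >= constraints$tm_window[1] && tm <= constraints$tm_window[2] &&
    gc >= constraints$gc_window[1] && gc <= constraints$gc_window[2] &&
    max_homopolymer_run(seq) <= constraints$max_homopolymer
}

#' Enumerate primer candidates anchored on a diagnostic SNP
#'
#' Generates one candidate per allowed length whose 3' terminal base sits
#' on the diagnostic column: forward candidates read the target-species
#' degenerate consensus up to (and ending at) the anchor; reverse
#' candidates are the reverse complement of the consensus slice starting at
#' the anchor, so their 3' base complements the target base. Candidates
#' containing gaps, exceeding the specific-primer degeneracy cap, or
#' failing the Tm/GC/homopolymer filters are dropped. An anchor too close
#' to the alignment edge yields an empty list with a `reason` attribute,
#' not an error.
#'
#' @param aln A `species_alignment`.
#' @param site One diagnostic site: a one-row tibble from
#'   [find_diagnostic_sites()] (columns column, target_species,
#'   target_base).
#' @param orientation `"forward"` or `"reverse"`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @param consensus Optional precomputed degenerate consensus of the target
#'   species (a cache used by [design_panel()]).
#' @return Candidate tibble sorted by distance of Tm from the window
#'   midpoint (then length).
#' @export
enumerate_anchored_primers <- function(aln, site,
                                       orientation = c("reverse", "forward"),
                                       constraints = design_constraints(),
                                       thermo = thermo_config(),
                                       consensus = NULL) {
  orientation <- match.arg(orientation)
  site <- as_tibble(site)[1, ]
  cons <- consensus %||%
    species_consensus(aln, site$target_species, "degenerate")
  n <- str_length(cons)
  a <- site$column # 0-based anchor column
  Ls <- seq.int(constraints$primer_len[1], constraints$primer_len[2])
  Ls <- if (orientation == "forward") Ls[a - Ls + 1L >= 0L] else
    Ls[a + Ls <= n]
  if (!length(Ls)) {
    return(empty_candidates(sprintf(
      "anchor column %d too close to the alignment edge (%s)",
      a + 1L, orientation)))
  }
  slices <- if (orientation == "forward")
    substring(cons, a - Ls + 2L, a + 1L) else substring(cons, a + 1L, a + Ls)
  keep <- !grepl("-", slices, fixed = TRUE)
  Ls <- Ls[keep]
  pseq <- vapply(slices[keep], function(s)
    if (orientation == "forward") s else reverse_complement(s), "",
    USE.NAMES = FALSE)
  deg <- vapply(pseq, degeneracy_of, 0, USE.NAMES = FALSE)
  keep <- deg <= constraints$max_specific_degeneracy
  cand <- tibble(sequence = pseq[keep], length = Ls[keep],
                 degeneracy = deg[keep])
  if (nrow(cand)) {
    cand$tm <- primer_tm(cand$sequence, cfg = thermo)
    cand$gc <- vapply(cand$sequence, gc_content, 0, USE.NAMES = FALSE)
    cand$run <- vapply(cand$sequence, max_homopolymer_run, 0,
                       USE.NAMES = FALSE)
    cand <- cand[cand$tm >= constraints$tm_window[1] &
                   cand$tm <= constraints$tm_window[2] &
                   cand$gc >= constraints$gc_window[1] &
                   cand$gc <= constraints$gc_window[2] &
                   cand$run <= constraints$max_homopolymer, , drop = FALSE]
  }
  if (!nrow(cand)) {
    return(empty_candidates(sprintf(
      "no candidate at anchor column %d (%s): edge/gap/degeneracy/filters",
      a + 1L, orientation)))
  }
  mid <- mean(constraints$tm_window)
  tibble(name = sprintf("%s_%s_a%d_L%d",
                        gsub("[^A-Za-z0-9]", "", site$target_species),
                        if (orientation == "forward") "F" else "R",
                        a + 1L, cand$length),
         sequence = cand$sequence, species = site$target_species,
         orientation = orientation, anchor_column = as.integer(a),
         tm = cand$tm, gc = cand$gc, length = as.integer(cand$length),
         degeneracy = cand$degeneracy) |>
    arrange(abs(.data$tm - mid), .data$length, .data$name)
}

#' Rank consensus common-primer candidates
#'
#' Builds a candidate from every conserved window (computed across all
#' species), in the requested orientation, and ranks by (degeneracy
#' ascending, |Tm - window midpoint| ascending) with a stable deterministic
#' order.
#'
#' @param aln A `species_alignment`.
#' @param windows Conserved windows tibble; defaults to
#'   [conserved_windows()] under the constraint caps.
#' @param orientation `"forward"` or `"reverse"`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @param max_candidates Rank at most this many windows after the
#'   degeneracy sort (keeps Tm evaluation cheap on long alignments).
#' @return Ranked candidate tibble (possibly empty, with a `reason`
#'   attribute).
#' @export
select_common_primer <- function(aln, windows = NULL,
                                 orientation = c("forward", "reverse"),
                                 constraints = design_constraints(),
                                 thermo = thermo_config(),
                                 max_candidates = 200L) {
  orientation <- match.arg(orientation)
  if (is.null(windows)) {
    windows <- conserved_windows(aln, constraints$primer_len,
                                 constraints$max_common_degeneracy)
  }
  windows <- windows[windows$degeneracy <= constraints$max_common_degeneracy, ]
  if (!nrow(windows)) {
    return(empty_candidates("no conserved window within the degeneracy cap"))
  }
  windows <- head(arrange(windows, .data$degeneracy, .data$start, .data$end),
                  max_candidates)
  pseq <- if (orientation == "forward") windows$consensus else
    vapply(windows$consensus, reverse_complement, "", USE.NAMES = FALSE)
  tm <- primer_tm(pseq, cfg = thermo)
  gc <- vapply(pseq, gc_content, 0, USE.NAMES = FALSE)
  run <- vapply(pseq, max_homopolymer_run, 0, USE.NAMES = FALSE)
  keep <- tm >= constraints$tm_window[1] & tm <= constraints$tm_window[2] &
    gc >= constraints$gc_window[1] & gc <= constraints$gc_window[2] &
    run <= constraints$max_homopolymer
  if (!any(keep)) {
    return(empty_candidates("no conserved window passed the primer filters"))
  }
  windows <- windows[keep, ]
  rows <- tibble(
    name = sprintf("common_%s_w%d_L%d",
                   if (orientation == "forward") "F" else "R",
                   windows$start + 1L, windows$end - windows$start),
    sequence = pseq[keep], species = "universal",
    orientation = orientation, anchor_column = NA_integer_,
    tm = tm[keep], gc = gc[keep],
    length = as.integer(windows$end - windows$start),
    degeneracy = windows$degeneracy,
    window_start = windows$start, window_end = windows$end)
  mid <- mean(constraints$tm_window)
  arrange(rows, .data$degeneracy, abs(.data$tm - mid), .data$name)
}

# expected amplicons of (common, each specific candidate) on one species'
# aligned consensus template: analytic 5'-to-5' spans from the anchor and
# window coordinates where available (gaps stripped before measuring),
# engine-scan fallback otherwise
expected_products_for <- function(common, cands, template, thermo,
                                  constraints) {
  template <- normalize_seq(template)
  ch <- seq_chars(template)
  gap <- ch == "-"
  u <- cumsum(!gap) - 1L # 0-based ungapped index per aligned column
  ungapped <- paste(ch[!gap], collapse = "")
  cs <- ce <- NA_integer_
  ws <- common$window_start
  if (!is.null(ws) && !is.na(ws[1]) && common$window_end[1] <= length(ch)) {
    wcols <- (ws[1] + 1L):common$window_end[1]
    if (!any(gap[wcols])) {
      cs <- u[wcols[1]]
      ce <- u[wcols[length(wcols)]] + 1L
    }
  }
  if (is.na(cs)) {
    sites <- find_binding_sites(common, ungapped)
    want <- if (common$orientation == "forward") "+" else "-"
    sites <- sites[sites$strand == want, ]
    if (nrow(sites) != 1L) return(NULL)
    cs <- sites$start[1]
    ce <- sites$end[1]
  }
  # engine pair scan for candidates without a recorded anchor (rare)
  slow <- cands[is.na(cands$anchor_column), , drop = FALSE]
  slow_rows <- purrr::map_dfr(seq_len(nrow(slow)), function(i) {
    amp <- expected_product(common, slow[i, ], ungapped, thermo,
                            constraints$max_amplicon)
    if (is.null(amp) || amp$length < constraints$min_amplicon) return(NULL)
    bind_cols(slow[i, ], tibble(exp_length = amp$length,
                                exp_tm = amp$product_tm,
                                exp_sequence = amp$sequence))
  })

  cands <- cands[!is.na(cands$anchor_column), , drop = FALSE]
  if (!nrow(cands)) return(slow_rows)
  # vectorized analytic spans for anchored candidates
  a <- cands$anchor_column
  L <- cands$length
  is_rev <- cands$orientation == "reverse"
  col1 <- ifelse(is_rev, a + 1L, a - L + 2L) # 1-based aligned footprint
  col2 <- ifelse(is_rev, a + L, a + 1L)
  nch <- length(ch)
  gcum <- c(0L, cumsum(gap))
  ok <- col1 >= 1L & col2 <= nch
  ok[ok] <- (gcum[col2[ok] + 1L] - gcum[col1[ok]]) == 0L # gap-free
  start_u <- end_u <- rep(NA_integer_, nrow(cands))
  w <- which(ok & is_rev)
  if (length(w)) {
    conv <- u[col1[w]] >= ce # reverse footprint fully downstream
    start_u[w] <- cs
    end_u[w] <- u[col2[w]] + 1L
    ok[w[!conv]] <- FALSE
  }
  w <- which(ok & !is_rev)
  if (length(w)) {
    conv <- cs >= u[col2[w]] + 1L
    start_u[w] <- u[col1[w]]
    end_u[w] <- ce
    ok[w[!conv]] <- FALSE
  }
  len <- end_u - start_u
  ok <- ok & !is.na(len) & len >= constraints$min_amplicon &
    len <= constraints$max_amplicon & len >= 50L
  if (!any(ok)) return(slow_rows)
  kept <- cands[ok, , drop = FALSE]
  seqp <- substring(ungapped, start_u[ok] + 1L, end_u[ok])
  fast_rows <- bind_cols(kept,
                         tibble(exp_length = as.integer(len[ok]),
                                exp_tm = product_tm(seqp, cfg = thermo),
                                exp_sequence = seqp))
  bind_rows(slow_rows, fast_rows)
}

# expected product of (common, specific) on the species' concrete template:
# exactly one clean product or NA row
expected_product <- function(common, specific, template, thermo,
                             max_amplicon) {
  tmp_panel <- new_primer_panel(common, specific, "gel",
                                tibble(species = specific$species,
                                       length = NA_integer_,
                                       product_tm = NA_real_),
                                "tmp", thermo)
  amps <- simulate_multiplex(tmp_panel, tibble(id = "t", sequence = template),
                             max_amplicon = max_amplicon)
  if (nrow(amps) != 1L) return(NULL)
  amps
}

#' Assemble a multiplex panel from candidate primers
#'
#' For each common candidate (in rank order) the expected amplicon of every
#' specific candidate is computed by running the in-silico PCR engine on
#' that species' ungapped consensus template (amplicon length is the
#' 5'-to-5' span including both primers). A depth-first search with
#' pruning then looks for a one-per-species selection whose amplicons lie
#' within the length bounds and differ pairwise by at least
#' `min_band_spacing` nt (melt mode additionally requires product-Tm
#' differences of at least `min_tm_separation`). Among feasible
#' assignments the minimum pairwise spacing is maximized (melt mode breaks
#' ties on minimum Tm separation, then lexicographic primer names); the
#' first common candidate admitting a feasible assignment wins. The search
#' is exhaustive while the combination count stays at or below
#' `exhaustive_limit`, else candidate lists are truncated to `beam_width`
#' per species (in rank order).
#'
#' @param common_candidates Ranked tibble from [select_common_primer()].
#' @param specific_candidates Candidate tibble covering every species
#'   (from [enumerate_anchored_primers()], possibly row-bound over sites).
#' @param templates Tibble species, sequence: one concrete ungapped
#'   template per species (e.g. [species_consensus()] majority).
#' @param mode `"gel"` or `"melt"`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @param max_common_tried Commons tried before giving up (default 5).
#' @param exhaustive_limit,beam_width Search-size controls (defaults 1e6
#'   and 50), fixed and logged for reproducibility.
#' @return A `primer_panel`, or a `panel_failure` object naming the first
#'   violated constraint per best partial assignment.
#' @export
assemble_panel <- function(common_candidates, specific_candidates, templates,
                           mode = c("gel", "melt"),
                           constraints = design_constraints(),
                           thermo = thermo_config(),
                           max_common_tried = 5L,
                           exhaustive_limit = 1e6, beam_width = 50L) {
  mode <- match.arg(mode)
  templates <- as_tibble(templates)
  species <- sort(unique(templates$species))
  if (!nrow(common_candidates)) {
    return(panel_failure(mode, "no common-primer candidate", tibble()))
  }
  empty_sp <- species[!species %in% specific_candidates$species]
  if (length(empty_sp)) {
    return(panel_failure(mode, sprintf(
      "empty candidate list for species: %s",
      paste(empty_sp, collapse = ", ")), tibble()))
  }

  diag_rows <- vector("list", 0L)
  for (ci in seq_len(min(nrow(common_candidates), max_common_tried))) {
    common <- common_candidates[ci, ]
    # per-species tables of (candidate, expected length, product tm)
    tabs <- purrr::map(species, function(sp) {
      cands <- specific_candidates[specific_candidates$species == sp &
                                     specific_candidates$orientation !=
                                       common$orientation, ]
      if (!nrow(cands)) return(NULL) # must converge: opposite orientations
      template <- templates$sequence[templates$species == sp][1]
      expected_products_for(common, cands, template, thermo, constraints)
    })
    names(tabs) <- species
    n_per <- vapply(tabs, function(t) if (is.null(t)) 0L else nrow(t), 0L)
    diag_rows[[length(diag_rows) + 1L]] <- tibble(
      common = common$name, species = species, n_products = n_per)
    if (any(n_per == 0L)) next

    if (prod(n_per) > exhaustive_limit) {
      tabs <- purrr::map(tabs, ~head(.x, beam_width))
    }
    # dedupe identical (length, tm) keys keeping the best-ranked candidate
    tabs <- purrr::map(tabs, function(t) {
      t[!duplicated(t[, c("exp_length", "exp_tm")]), , drop = FALSE]
    })

    sel <- search_assignment(tabs, mode, constraints)
    if (is.null(sel)) next

    specifics <- bind_rows(purrr::map2(tabs, sel, ~.x[.y, ])) |>
      select(!dplyr::starts_with("exp_"))
    expected <- bind_rows(purrr::map2(tabs, sel, ~.x[.y, ])) |>
      transmute(species = .data$species,
                length = as.integer(.data$exp_length),
                product_tm = .data$exp_tm,
                sequence = .data$exp_sequence)
    return(new_primer_panel(common, specifics, mode, expected,
                            gene_label = "designed", thermo = thermo,
                            constraints = constraints))
  }
  panel_failure(mode, sprintf(
    "no feasible one-per-species assignment under %s constraints (spacing >= %g%s)",
    mode, constraints$min_band_spacing,
    if (mode == "melt") sprintf(", dTm >= %g", constraints$min_tm_separation)
    else ""),
    bind_rows(diag_rows))
}

# DFS over one-per-species picks maximizing min pairwise spacing (melt:
# then min pairwise dTm), pruning branches violating pairwise constraints.
search_assignment <- function(tabs, mode, constraints) {
  k <- length(tabs)
  best <- NULL
  best_key <- c(-Inf, -Inf)
  idx <- integer(k)
  names_of <- function(sel) {
    paste(purrr::map2_chr(tabs, sel, ~.x$name[.y]), collapse = "|")
  }
  recurse <- function(level, lens, tms) {
    if (level > k) {
      key <- c(min(abs(outer(lens, lens, "-"))[upper.tri(diag(k))]),
               if (mode == "melt")
                 min(abs(outer(tms, tms, "-"))[upper.tri(diag(k))]) else 0)
      sel <- idx[seq_len(k)]
      if (key[1] > best_key[1] + 1e-9 ||
          (abs(key[1] - best_key[1]) <= 1e-9 && key[2] > best_key[2] + 1e-9) ||
          (abs(key[1] - best_key[1]) <= 1e-9 &&
           abs(key[2] - best_key[2]) <= 1e-9 && !is.null(best) &&
           names_of(sel) < names_of(best))) {
        best <<- sel
        best_key <<- key
      }
      return(invisible())
    }
    t <- tabs[[level]]
    for (i in seq_len(nrow(t))) {
      l <- t$exp_length[i]
      tm <- t$exp_tm[i]
      ok <- all(abs(lens - l) >= constraints$min_band_spacing)
      if (ok && mode == "melt") {
        ok <- all(abs(tms - tm) >= constraints$min_tm_separation)
      }
      if (!ok) next
      idx[level] <<- i
      recurse(level + 1L, c(lens, l), c(tms, tm))
    }
  }
  recurse(1L, numeric(0), numeric(0))
  best
}

panel_failure <- function(mode, reason, details) {
  structure(list(mode = mode, reason = reason, details = details),
            class = "panel_failure")
}

#' @export
print.panel_failure <- function(x, ...) {
  cat(sprintf("<panel_failure> %s mode: %s\n", x$mode, x$reason))
  if (nrow(x$details)) print(x$details)
  invisible(x)
}

#' Is a panel-design result a success?
#' @param x Result of [assemble_panel()] or [design_panel()].
#' @return TRUE for a `primer_panel`, FALSE for a `panel_failure`.
#' @export
panel_ok <- function(x) inherits(x, "primer_panel")

#' One-call panel design from an alignment
#'
#' Full pipeline: strict diagnostic-site discovery, SNP-anchored specific
#' enumeration, conserved-window common selection, assembly. With
#' `orientation = "auto"` a common-forward + specific-reverse design is
#' tried first, then the mirrored common-reverse + specific-forward design.
#'
#' @param aln A `species_alignment` (>= 2 species).
#' @param mode `"gel"` or `"melt"`.
#' @param orientation `"auto"`, `"common_forward"` or `"common_reverse"`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @param gene_label Free-text label stored in the panel.
#' @return A `primer_panel` or a `panel_failure`.
#' @export
design_panel <- function(aln, mode = c("gel", "melt"),
                         orientation = c("auto", "common_forward",
                                         "common_reverse"),
                         constraints = design_constraints(),
                         thermo = thermo_config(),
                         gene_label = "barcode") {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  sites <- find_all_diagnostic_sites(aln)
  # aligned majority consensus per species; assembly strips gaps when
  # measuring spans
  templates <- tibble(
    species = species_levels(aln),
    sequence = vapply(species_levels(aln), function(sp)
      species_consensus(aln, sp, "majority"), ""))
  windows <- conserved_windows(aln, constraints$primer_len,
                               constraints$max_common_degeneracy)
  arms <- switch(orientation,
                 auto = c("common_forward", "common_reverse"),
                 orientation)
  last_failure <- NULL
  for (arm in arms) {
    common_ori <- if (arm == "common_forward") "forward" else "reverse"
    spec_ori <- if (arm == "common_forward") "reverse" else "forward"
    commons <- select_common_primer(aln, windows, common_ori, constraints,
                                    thermo)
    cons_cache <- purrr::map(setNames(species_levels(aln),
                                      species_levels(aln)),
                             function(sp)
                               species_consensus(aln, sp, "degenerate"))
    specifics <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      enumerate_anchored_primers(aln, sites[i, ], spec_ori, constraints,
                                 thermo,
                                 consensus = cons_cache[[
                                   sites$target_species[i]]])
    })
    if (!nrow(specifics)) {
      last_failure <- panel_failure(mode, sprintf(
        "no %s specific-primer candidates", spec_ori), tibble())
      next
    }
    res <- assemble_panel(commons, specifics, templates, mode, constraints,
                          thermo)
    if (panel_ok(res)) {
      res$gene_label <- gene_label
      return(res)
    }
    last_failure <- res
  }
  last_failure
}
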