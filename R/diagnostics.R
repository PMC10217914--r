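# Diagnostic-site discovery: alignment columns fixed within one target
# species and never observed in any other species. These columns anchor the
# 3' terminus of species-specific primers, which is what makes extension --
# and therefore amplification -- species-conditional.

#' Find species-diagnostic alignment columns
#'
#' Strict mode: a column qualifies when every target record carries one
#' unambiguous base (ambiguity codes count as "not fixed") and that base is
#' never covered by any non-target record (non-target ambiguity codes are
#' expanded before the test, so a non-target Y blocks both C and T).
#' Frequency mode relaxes fixation to a within-target majority of at least
#' `min_freq` while keeping the absence test strict.
#'
#' @param aln A `species_alignment` with at least two species.
#' @param target Species whose diagnostic sites are wanted.
#' @param mode `"strict"` (default) or `"frequency"`.
#' @param min_freq Minimum within-target frequency of the candidate base in
#'   frequency mode (default 1.0).
#' @return Tibble, one row per diagnostic column, sorted by column:
#'   column (0-based), target_species, target_base, other_bases (collapsed
#'   string of bases seen in non-targets), fixed_in_target,
#'   absent_in_others.
#' @export
find_diagnostic_sites <- function(aln, target,
                                  mode = c("strict", "frequency"),
                                  min_freq = 1.0) {
  mode <- match.arg(mode)
  if (!target %in% aln$species) {
    abort(sprintf("target species '%s' not in alignment", target))
  }
  if (length(species_levels(aln)) < 2L) {
    abort("single-species alignment: nothing to discriminate against")
  }
  m <- alignment_matrix(aln)
  in_target <- aln$species == target
  tm <- m[in_target, , drop = FALSE]
  om <- m[!in_target, , drop = FALSE]

  rows <- vector("list", 0L)
  for (j in seq_len(ncol(m))) {
    tcol <- tm[, j]
    base <- NA_character_
    if (mode == "strict") {
      u <- unique(tcol)
      if (length(u) == 1L && u %in% c("A", "C", "G", "T")) base <- u
    } else {
      concrete <- tcol[tcol %in% c("A", "C", "G", "T")]
      if (length(concrete)) {
        tt <- sort(table(concrete), decreasing = TRUE)
        cand <- names(tt)[1]
        if (tt[1] / length(tcol) >= min_freq) base <- cand
      }
    }
    if (is.na(base)) next
    ocol <- om[, j]
    other_bases <- unique(unlist(IUPAC_SETS[ocol[ocol != "-"]],
                                 use.names = FALSE))
    if (base %in% other_bases) next
    rows[[length(rows) + 1L]] <- tibble(
      column = j - 1L, target_species = target, target_base = base,
      other_bases = paste(sort(other_bases), collapse = ""),
      fixed_in_target = length(unique(tcol)) == 1L,
      absent_in_others = TRUE)
  }
  if (!length(rows)) {
    return(tibble(column = integer(), target_species = character(),
                  target_base = character(), other_bases = character(),
                  fixed_in_target = logical(), absent_in_others = logical()))
  }
  bind_rows(rows) |> arrange(.data$column)
}

#' Diagnostic sites for every species in an alignment
#'
#' @inheritParams find_diagnostic_sites
#' @return Tibble of sites for all species, sorted by species then column.
#' @export
find_all_diagnostic_sites <- function(aln, mode = "strict", min_freq = 1.0) {
  purrr::map_dfr(species_levels(aln), function(sp) {
    find_diagnostic_sites(aln, sp, mode = mode, min_freq = min_freq)
  }) |> arrange(.data$target_species, .data$column)
}

#' Per-species diagnosability summary
#'
#' Counts strict diagnostic sites per species and flags species with none
#' (for which a strict-mode panel is impossible). Reported columns are
#' 1-based inclusive, as in all user-facing output.
#'
#' @param aln A `species_alignment` with at least two species.
#' @return Tibble: species, n_strict_sites, columns_1based (collapsed
#'   string), zero_sites flag.
#' @export
diagnosability_report <- function(aln) {
  if (length(species_levels(aln)) < 2L) {
    abort("need at least two species")
  }
  purrr::map_dfr(species_levels(aln), function(sp) {
    sites <- find_diagnostic_sites(aln, sp, mode = "strict")
    tibble(species = sp,
           n_strict_sites = nrow(sites),
           columns_1based = paste(sites$column + 1L, collapse = ","),
           zero_sites = nrow(sites) == 0L)
  })
}
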