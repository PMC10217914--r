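# Synthetic multi-species barcode fixtures with planted structure: an
# ancestral random sequence, per-species fixed diagnostic substitutions at
# reserved non-overlapping columns, Poisson-thinned intraspecific noise
# avoiding the reserved columns, and mutation-free flanks emulating the
# universal priming sites at both ends of a barcode amplicon.

#' Specification of a synthetic barcode fixture
#'
#' Defaults emulate a four-species mitochondrial barcode study: 4 species,
#' 10 sequenced haplotypes each, a 655-column CO1-like alignment (use 464
#' for a CYTB-like region), 6 planted diagnostic sites per species and a
#' low intraspecific substitution rate.
#'
#' @param n_species Number of species (default 4).
#' @param haplotypes_per_species Records per species (default 10).
#' @param barcode_length Alignment columns (default 655; CYTB-like: 464).
#' @param n_diagnostic_sites Planted diagnostic columns per species
#'   (default 6), non-overlapping across species.
#' @param intraspecific_mut_rate Per-site substitution probability per
#'   haplotype, in `[0, 0.02]`; substitutions avoid reserved diagnostic
#'   columns and the conserved flanks.
#' @param universal_flank Keep the outer `flank_width` columns
#'   substitution-free across all records (universal priming sites).
#' @param flank_width Width of each conserved flank (default 30).
#' @param edge_margin Reserved diagnostic columns are kept at least this
#'   far from the alignment edges so anchored primers always fit
#'   (default 25, the longest primer).
#' @param seed Integer seed; the same spec is byte-identical across runs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_species = 4L, haplotypes_per_species = 10L,
                         barcode_length = 655L, n_diagnostic_sites = 6L,
                         intraspecific_mut_rate = 0.005,
                         universal_flank = TRUE, flank_width = 30L,
                         edge_margin = 25L, seed = 1L) {
  if (intraspecific_mut_rate < 0 || intraspecific_mut_rate > 0.02) {
    abort("intraspecific_mut_rate must lie in [0, 0.02]")
  }
  if (n_species < 2L) abort("need at least 2 species")
  spec <- structure(list(
    n_species = as.integer(n_species),
    haplotypes_per_species = as.integer(haplotypes_per_species),
    barcode_length = as.integer(barcode_length),
    n_diagnostic_sites = as.integer(n_diagnostic_sites),
    intraspecific_mut_rate = intraspecific_mut_rate,
    universal_flank = isTRUE(universal_flank),
    flank_width = as.integer(flank_width),
    edge_margin = as.integer(edge_margin),
    seed = as.integer(seed)), class = "fixture_spec")
  reserved_lo <- max(spec$edge_margin, if (spec$universal_flank)
    spec$flank_width else 0L)
  usable <- spec$barcode_length - 2L * reserved_lo
  if (spec$n_species * spec$n_diagnostic_sites > usable %/% 2L) {
    abort(sprintf(
      "too many reserved columns (%d) for barcode length %d",
      spec$n_species * spec$n_diagnostic_sites, spec$barcode_length))
  }
  spec
}

fixture_species_names <- function(n) paste0("species_", LETTERS[seq_len(n)])

#' Generate a synthetic species set with planted diagnostic sites
#'
#' One ancestral uniform-random sequence; each species receives
#' `n_diagnostic_sites` fixed substitutions at reserved columns unique to
#' it (so each planted column is strict-diagnostic by construction); each
#' haplotype then receives Poisson-thinned intraspecific substitutions
#' that avoid all reserved columns and the conserved flanks. Record ids
#' are `species|hapNN`, so the default FASTA header rule recovers the
#' species label.
#'
#' @param spec A [fixture_spec()].
#' @return List with `alignment` (a `species_alignment`) and `truth`
#'   (tibble species, column (0-based), target_base, ancestral_base).
#' @export
generate_species_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  bases <- c("A", "C", "G", "T")
  with_seed(spec$seed, {
    n <- spec$barcode_length
    anc <- sample(bases, n, replace = TRUE)
    lo <- max(spec$edge_margin, if (spec$universal_flank)
      spec$flank_width else 0L)
    eligible <- (lo + 1L):(n - lo) # 1-based columns eligible for planting
    reserved <- sort(sample(eligible,
                            spec$n_species * spec$n_diagnostic_sites))
    species <- fixture_species_names(spec$n_species)
    assignment <- split(reserved, sample(rep(species,
                                             each = spec$n_diagnostic_sites)))
    protected <- c(seq_len(lo), (n - lo + 1L):n, reserved)
    mutable <- setdiff(seq_len(n), protected)

    truth <- purrr::map_dfr(species, function(sp) {
      cols <- assignment[[sp]]
      tb <- vapply(cols, function(j) sample(setdiff(bases, anc[j]), 1L), "")
      tibble(species = sp, column = cols - 1L, target_base = tb,
             ancestral_base = anc[cols])
    })

    recs <- purrr::map_dfr(species, function(sp) {
      base_seq <- anc
      tt <- truth[truth$species == sp, ]
      base_seq[tt$column + 1L] <- tt$target_base
      purrr::map_dfr(seq_len(spec$haplotypes_per_species), function(h) {
        hap <- base_seq
        if (spec$intraspecific_mut_rate > 0 && length(mutable)) {
          k <- rpois(1L, spec$intraspecific_mut_rate * length(mutable))
          k <- min(k, length(mutable))
          if (k > 0) {
            hit <- sample(mutable, k)
            hap[hit] <- vapply(hit, function(j)
              sample(setdiff(bases, hap[j]), 1L), "")
          }
        }
        tibble(id = sprintf("%s|hap%02d", sp, h), species = sp,
               sequence = paste(hap, collapse = ""))
      })
    })
    list(alignment = species_alignment(recs$id, recs$species, recs$sequence),
         truth = arrange(truth, .data$species, .data$column))
  })
}

#' Synthetic template flanked by universal priming sites
#'
#' Emits a concrete template embedding an exact match to the forward
#' universal primer and the reverse complement of the reverse universal
#' primer, positioned so the 5'-to-5' span is exactly the canonical
#' barcode amplicon size (655 nt for the CO1 pair, 464 for CYTB), with
#' random sequence between and random flanks outside. Degenerate universal
#' primers are embedded as one concrete expansion drawn under the seed.
#'
#' @param gene_mode `"co1"` or `"cytb"`; sets the universal pair and span
#'   from [universal_barcode_primers()] unless overridden.
#' @param universal_fwd,universal_rev Override primer sequences.
#' @param span Override the 5'-to-5' span.
#' @param flank Random flank length added on each side (default 100).
#' @param seed Integer seed.
#' @return A single template sequence string.
#' @export
generate_flanked_template <- function(gene_mode = c("co1", "cytb"),
                                      universal_fwd = NULL,
                                      universal_rev = NULL, span = NULL,
                                      flank = 100L, seed = 1L) {
  gene_mode <- match.arg(gene_mode)
  up <- universal_barcode_primers()
  gene <- toupper(gene_mode)
  pair <- up[up$gene == gene, ]
  universal_fwd <- universal_fwd %||%
    pair$sequence[pair$orientation == "forward"]
  universal_rev <- universal_rev %||%
    pair$sequence[pair$orientation == "reverse"]
  span <- span %||% pair$span[1]
  mid_len <- span - str_length(universal_fwd) - str_length(universal_rev)
  if (mid_len < 0) {
    abort(sprintf("span %d shorter than the combined primer lengths", span))
  }
  with_seed(seed, {
    left <- sample(expand_degenerate(universal_fwd), 1L)
    right <- reverse_complement(sample(expand_degenerate(universal_rev), 1L))
    rnd <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                    replace = TRUE), collapse = "")
    paste0(rnd(flank), left, rnd(mid_len), right, rnd(flank))
  })
}

#' Write a fixture to disk (FASTA + truth TSV)
#'
#' @param fix Result of [generate_species_set()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "alignment.fasta")
  truth <- file.path(dir, "truth.tsv")
  write_species_alignment(fix$alignment, fasta)
  out <- fix$truth |>
    transmute(species = .data$species, column_1based = .data$column + 1L,
              target_base = .data$target_base,
              ancestral_base = .data$ancestral_base)
  utils::write.table(out, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(alignment = fasta, truth = truth))
}
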