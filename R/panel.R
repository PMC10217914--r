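# The primer_panel object: one common (consensus) primer plus one
# species-specific primer per species, in converging orientations, with the
# per-species expected amplicon (length, and predicted product Tm in melt
# mode). Readout mode "gel" separates species by band size; "melt" by
# product melting temperature (and still by size, so a gel can confirm).

new_primer_panel <- function(common, specifics, mode, expected, gene_label,
                             thermo = thermo_config(),
                             constraints = design_constraints()) {
  structure(list(common = common,
                 specifics = arrange(specifics, .data$species),
                 mode = mode,
                 expected = arrange(expected, .data$species),
                 gene_label = gene_label,
                 thermo = thermo,
                 constraints = constraints),
            class = "primer_panel")
}

#' All primers of a panel as one tibble
#' @param panel A `primer_panel`.
#' @return Tibble with the common primer first, then specifics by species.
#' @export
panel_primers <- function(panel) {
  bind_rows(panel$common, panel$specifics)
}

# panel restricted to the common primer + one species' specific
subset_panel <- function(panel, species) {
  keep <- panel$specifics$species == species
  new_primer_panel(panel$common, panel$specifics[keep, , drop = FALSE],
                   panel$mode, panel$expected[panel$expected$species ==
                                                species, , drop = FALSE],
                   panel$gene_label, panel$thermo, panel$constraints)
}

#' @export
print.primer_panel <- function(x, ...) {
  cat(sprintf("<primer_panel> %s mode, %s | common %s + %d specifics\n",
              x$mode, x$gene_label, x$common$name, nrow(x$specifics)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a primer panel into a published-table layout
#'
#' One row per primer with name, sequence, model Tm, expected amplicon
#' length, gene target and targeted organism (the layout of a primer table
#' in a methods paper).
#'
#' @param x A `primer_panel`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.primer_panel <- function(x, ...) {
  p <- panel_primers(x)
  exp_len <- setNames(x$expected$length, x$expected$species)
  exp_tm <- setNames(x$expected$product_tm, x$expected$species)
  tibble(name = p$name,
         sequence = p$sequence,
         orientation = p$orientation,
         tm = p$tm,
         amplicon_length = ifelse(p$species == "universal", NA_integer_,
                                  as.integer(exp_len[p$species])),
         product_tm = ifelse(p$species == "universal", NA_real_,
                             as.numeric(exp_tm[p$species])),
         gene_target = x$gene_label,
         targeted_organism = p$species)
}

#' @export
glance.primer_panel <- function(x, ...) {
  lens <- x$expected$length
  tms <- x$expected$product_tm
  pair_min <- function(v) {
    if (length(v) < 2L || anyNA(v)) return(NA_real_)
    min(abs(outer(v, v, "-"))[upper.tri(diag(length(v)))])
  }
  tibble(mode = x$mode, gene_label = x$gene_label,
         n_species = nrow(x$specifics),
         common = x$common$name,
         min_length_spacing = pair_min(as.numeric(lens)),
         min_product_tm_separation = pair_min(tms))
}

#' Serialize / load a panel as YAML
#'
#' The YAML file carries primers, orientations, mode, expected amplicons
#' and the thermodynamic model identifiers, and is the format the scanner
#' consumes.
#'
#' @param panel A `primer_panel`.
#' @param path Output path.
#' @return `path` (write) or a `primer_panel` (read).
#' @export
write_panel_yaml <- function(panel, path) {
  obj <- list(
    gene_label = panel$gene_label,
    mode = panel$mode,
    thermo = unclass(panel$thermo),
    common = as.list(panel$common),
    specifics = purrr::transpose(as.list(panel$specifics)) |>
      purrr::map(~.x),
    expected = purrr::transpose(as.list(panel$expected)) |> purrr::map(~.x))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_panel_yaml
#' @export
read_panel_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  thermo <- do.call(thermo_config, obj$thermo)
  common <- as_tibble(obj$common)
  specifics <- bind_rows(lapply(obj$specifics, as_tibble))
  expected <- bind_rows(lapply(obj$expected, as_tibble))
  new_primer_panel(common, specifics, obj$mode, expected, obj$gene_label,
                   thermo = thermo)
}

#' Write a panel as a primer-table TSV
#'
#' Mirrors the column layout of a published primer table (Name, Sequence,
#' Tm, Amplicon Length, Gene Target, Targeted Organism) plus explicit
#' Orientation and Role columns.
#'
#' @param panel A `primer_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  td <- tidy(panel)
  out <- tibble(Name = td$name, Sequence = td$sequence,
                Tm = td$tm, Amplicon_Length = td$amplicon_length,
                Gene_Target = td$gene_target,
                Targeted_Organism = td$targeted_organism,
                Orientation = td$orientation,
                Role = ifelse(td$targeted_organism == "universal",
                              "common", "specific"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a panel from a primer-table TSV
#'
#' Expects the column layout of [write_panel_tsv()] (the shipped Mullidae
#' panels use it). Model Tm is recomputed under `thermo`; any Tm printed in
#' the file is kept as `tm_reported` (published Tm values come from
#' unstated models and serve as plausibility bands only).
#'
#' @param path TSV path.
#' @param mode Readout mode of the panel, `"gel"` or `"melt"`.
#' @param gene_label Free-text gene label; defaults to the Gene_Target
#'   column.
#' @param thermo A [thermo_config()].
#' @return A `primer_panel`.
#' @export
read_panel_tsv <- function(path, mode = c("gel", "melt"), gene_label = NULL,
                           thermo = thermo_config()) {
  mode <- match.arg(mode)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE) |> as_tibble()
  gene_label <- gene_label %||% raw$Gene_Target[1]
  prim <- tibble(
    name = raw$Name,
    sequence = vapply(raw$Sequence, normalize_seq, ""),
    species = ifelse(tolower(raw$Targeted_Organism) == "universal",
                     "universal", raw$Targeted_Organism),
    orientation = ifelse(toupper(substr(raw$Orientation, 1, 1)) == "F",
                         "forward", "reverse"),
    anchor_column = NA_integer_,
    tm = primer_tm(raw$Sequence, cfg = thermo),
    tm_reported = suppressWarnings(as.numeric(raw$Tm)),
    gc = vapply(raw$Sequence, gc_content, 0),
    length = str_length(raw$Sequence),
    degeneracy = vapply(raw$Sequence, function(s)
      degeneracy_of(normalize_seq(s)), 0))
  is_common <- prim$species == "universal"
  if (sum(is_common) != 1L) {
    abort("panel file must contain exactly one universal (common) primer")
  }
  expected <- tibble(species = prim$species[!is_common],
                     length = as.integer(raw$Amplicon_Length[!is_common]),
                     product_tm = NA_real_)
  new_primer_panel(prim[is_common, ], prim[!is_common, ], mode, expected,
                   gene_label, thermo = thermo)
}

#' The published Mullidae panels
#'
#' Loads the three shipped four-species panels for red mullet
#' authentication: the CO1 gel multiplex (amplicons 193/244/351/436 nt,
#' common forward + specific reverse primers), the CYTB gel multiplex
#' (106/147/291/351 nt, common reverse + specific forwards) and the CO1
#' melt-curve qPCR multiplex (154/256/353/438 nt).
#'
#' @param thermo A [thermo_config()].
#' @return Named list of three `primer_panel`s: co1_multiplex,
#'   cytb_multiplex, co1_melt.
#' @export
mullidae_panels <- function(thermo = thermo_config()) {
  dir <- system.file("extdata", "panels", package = "mulliplex")
  list(
    co1_multiplex = read_panel_tsv(file.path(dir, "co1_multiplex.tsv"),
                                   mode = "gel", thermo = thermo),
    cytb_multiplex = read_panel_tsv(file.path(dir, "cytb_multiplex.tsv"),
                                    mode = "gel", thermo = thermo),
    co1_melt = read_panel_tsv(file.path(dir, "co1_melt.tsv"),
                              mode = "melt", thermo = thermo))
}

#' Universal barcode primer pairs
#'
#' The published universal pairs used to amplify the barcode regions the
#' panels sit in: the fish CO1 barcode pair (655 nt 5'-to-5' span) and the
#' CYTB pair (464 nt span; both CYTB primers carry 5' restriction-site
#' tails, included verbatim).
#'
#' @return Tibble: name, sequence, gene, orientation, span.
#' @export
universal_barcode_primers <- function() {
  tibble(
    name = c("FISHCO1LBC", "FISHCO1HBC", "L14841", "H15149"),
    sequence = c("TCAACYAATCAYAAAGATATYGGCAC",
                 "ACTTCYGGGTGRCCRAARAATCA",
                 "AAAAAGCTTCCATCCAACATCTCAGCATGATGAAA",
                 "AAACTGCAGCCCCTCAGAATGATATTTGTCCTCA"),
    gene = c("CO1", "CO1", "CYTB", "CYTB"),
    orientation = c("forward", "reverse", "forward", "reverse"),
    span = c(655L, 655L, 464L, 464L))
}

#' Synthetic reference templates for a panel
#'
#' Builds one synthetic barcode template per panel species that embeds the
#' panel's common primer and that species' specific primer at exactly the
#' panel's expected 5'-to-5' span, separated by random filler and flanked
#' by random sequence. These are constructed stand-ins for conspecific
#' reference records (no database is queried): the diagnostic 3' anchor of
#' every other species' specific primer is absent by construction, so a
#' correct engine amplifies exactly one product of the expected length per
#' template.
#'
#' @param panel A `primer_panel`.
#' @param seed Integer seed for the random filler.
#' @param flank Random flank length on each side (default 60).
#' @return Tibble: species, id, sequence.
#' @export
synthetic_panel_references <- function(panel, seed = 1L, flank = 60L) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(panel$expected)), function(i) {
      sp <- panel$expected$species[i]
      span <- panel$expected$length[i]
      spec <- panel$specifics[panel$specifics$species == sp, ]
      common <- panel$common
      if (common$orientation == "forward") {
        left <- sample(expand_degenerate(common$sequence), 1L)
        right <- reverse_complement(sample(expand_degenerate(spec$sequence), 1L))
      } else {
        left <- sample(expand_degenerate(spec$sequence), 1L)
        right <- reverse_complement(sample(expand_degenerate(common$sequence), 1L))
      }
      mid_len <- span - str_length(left) - str_length(right)
      if (mid_len < 0) abort(sprintf(
        "expected span %d shorter than the two primers for %s", span, sp))
      rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
      tibble(species = sp, id = paste0("synthetic_", gsub(" ", "_", sp)),
             sequence = paste0(rnd(flank), left, rnd(mid_len), right,
                               rnd(flank)))
    })
  })
}

# run thunk with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
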