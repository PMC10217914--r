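---
title: "Designing species-diagnostic multiplex PCR and melt-curve assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-diagnostic multiplex PCR and melt-curve assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulliplex)
library(tibble)
```

## The problem

Closely related fish traded side by side — here the four Mullidae species
sold as red mullet in Eastern Mediterranean markets (*Mullus barbatus*,
*M. surmuletus*, the invasive *Upeneus moluccensis* and the imported
*Pseudupeneus prayensis*) — are hard to tell apart morphologically once
filleted, frozen or cooked, which invites substitution fraud. Sanger
sequencing of a mitochondrial barcode settles identity but is slow and
costly per specimen. A one-tube alternative is a multiplex PCR built from
**one common primer** sitting in a region conserved across all species plus
**one species-specific primer per species**, each anchored on a diagnostic
SNP. Every specimen then yields a single product whose *size* (on an
agarose gel) or *melting temperature* (in a SYBR melt-curve qPCR)
identifies the species. `mulliplex` implements the full design and
in-silico validation workflow for such assays on any species-labeled
barcode alignment.

## The core model

**Diagnostic sites.** A column of the alignment is *strict-diagnostic* for
species $s$ when every record of $s$ carries one unambiguous base $b$ and
no record of any other species can carry $b$ (ambiguity codes in
non-target records are expanded before the test, so a non-target Y blocks
both C and T — the conservative reading). Placing a primer's 3′ terminus
on such a column makes polymerase extension, and hence amplification,
conditional on species identity. A frequency mode (`min_freq` < 1) exists
for exploratory work with polymorphic anchors; the strict default reflects
how such assays are actually deployed: the published Mullidae panels
observed no intraspecific variation at their anchors across 318 field
specimens.

**Binding model.** The in-silico PCR engine treats a primer position as
matching a template base iff the base lies in the IUPAC expansion of the
primer code. Binding requires the 3′-terminal `three_prime_exact_len`
bases (default 3) to match exactly, and tolerates at most
`max_internal_mismatches` (default 2) elsewhere. The 3′-exact window is
the mechanism of species specificity; the internal tolerance acknowledges
that real haplotypes drift away from the consensus a primer was designed
on. Both knobs are exposed because no wet-lab binding model is implied —
only the qualitative asymmetry between 3′ and internal mismatches.
Template `N` matches nothing unless a permissive-N flag is set, and gaps
never match.

**Primer Tm.** Oligo melting temperatures use SantaLucia (1998) unified
nearest-neighbor ΔH/ΔS with the Owczarzy (2004) monovalent-salt
correction, at 50 mM monovalent salt and 500 nM total primer by default;
divalent salt is folded in as the usual $120\sqrt{[\mathrm{Mg^{2+}}]}$
equivalent. Degenerate primers are scored as the mean over their concrete
expansions (the minimum is also reported as the conservative annealing
bound). Published primer-table Tm values routinely come from unstated
vendor models — the Mullidae table even prints two different Tm values for
one identical sequence — so the package records its own model identifiers
in every output and treats printed values as a ±5 °C plausibility band,
never as targets.

**Product Tm.** Amplicons (≥ 50 nt) use the empirical long-duplex formula

$$T_m = 81.5 + 16.6\log_{10}[\mathrm{Na^+}] + 0.41\,(\%GC) - 675/L.$$

Salt enters additively, so the pairwise product-Tm *differences* that
melt-mode design optimizes are salt-invariant.

## Panel design

Candidate specific primers are enumerated at every strict site, one per
allowed length (18–25 nt), reading the target-species degenerate consensus
so that low intraspecific polymorphism surfaces as Y/R codes (capped at
degeneracy 4 per primer). Candidates must pass Tm (50–65 °C), GC (30–70 %)
and homopolymer (≤ 5) filters. The common primer is drawn from conserved
windows computed across *all* species, capped at degeneracy 8 — enough for
the two-Y pattern seen in real universal barcode primers — and ranked by
(degeneracy, then distance of Tm from the window midpoint).

Assembly searches one-per-species selections against each species'
majority-consensus template. Amplicon length is the 5′-to-5′ span
including both primers, measured on the ungapped template. A gel-mode
panel requires all pairwise length differences ≥ 40 nt (the published
panels' smallest gap is 51 nt on a 2 % agarose gel, so 40 keeps
feasibility while remaining resolvable); a melt-mode panel additionally
requires all pairwise product-Tm differences ≥ 1.0 °C, and keeps the
length ladder so a gel can confirm the melt call. Among feasible
selections the search maximizes the *minimum* pairwise spacing (melt mode
breaks ties on minimum Tm separation, then on lexicographic primer
names) — maximizing the minimum gap is what makes a ladder readable, and
the deterministic tie-break makes reports byte-identical across runs.
Commons are tried in rank order and the first that admits a feasible
assignment wins. The search is exhaustive up to $10^6$ combinations and
truncates candidate lists to a beam of 50 per species beyond that; both
limits are fixed constants. Amplicons are bounded to 80–500 nt: below ~80
nt products approach primer-dimer territory, above 500 nt amplification
from degraded (fried!) tissue becomes unreliable.

Orientation is symmetric: common-forward with specific-reverse primers
(the CO1 panels) and common-reverse with specific-forwards (the CYTB
panel, whose common primer is the classic H-strand universal) are both
supported, and `design_panel(orientation = "auto")` tries both arms.

## Readout simulation and calling

*Virtual gel.* Migration is an affine map of $-\log_{10}(L)$ normalized to
the ladder extremes, so ordering equals length order; same-lane bands
within 10 nt are flagged co-migrating.

*Melt profiles.* The −dF/dT signal is a sum of unit-height Gaussians at
each product's predicted Tm, sampled on the 60–95 °C instrument grid at
0.3 °C. Two equal Gaussians are bimodal iff their centers differ by more
than $2\sigma$; at the default peak width σ = 0.8 °C that is 1.6 °C. The
1 °C design floor therefore does **not** guarantee two visible maxima
inside a single mixed reaction — it guarantees that the single peak each
specimen produces is assignable to exactly one species across reactions,
which is how the assay is read (one specimen, one product, one peak). The
tests assert this 2σ boundary numerically rather than pretending 1 °C
resolves within one profile.

*Calls.* Gel mode: exactly one band within ±15 nt of exactly one expected
length calls that species; no band is "no-amplification" (the negative
control outcome for non-target fish); anything else is "ambiguous". Melt
mode uses ±0.4 °C on peak Tm. Both tolerances sit well under half the
design gaps (51 nt, 1 °C), and are config-exposed. Cohort calls aggregate
into per-species one-vs-rest sensitivity and specificity, panel minima,
and discordant specimen ids.

*Standard curves.* Ct is regressed on $\log_{10}$ concentration;
efficiency is $10^{-1/\text{slope}} - 1$, so the perfect-doubling slope
$-1/\log_{10}2 = -3.3219$ gives 100 %. The dilution-series simulator used
in tests generates $Ct = b - 3.3219\log_{10}c + N(0,\sigma)$ over the
10 ng–1 pg ladder.

## The synthetic data generator

`generate_species_set()` plants known structure so every claim above is
testable without touching a database: one uniform-random ancestral
sequence (655 columns for a CO1-like region, 464 for CYTB-like); per
species a fixed number of diagnostic substitutions at reserved,
non-overlapping columns kept ≥ 25 nt from the edges so anchored primers
always fit; Poisson-thinned intraspecific substitutions (default rate
0.005/site, the "low polymorphism" regime of mitochondrial barcodes) that
avoid the reserved columns; and substitution-free 30-column flanks
emulating the universal priming sites that real barcode amplicons carry.
Because noise avoids the anchors, planted-site recovery is exact by
construction — the generator emulates the published finding that anchor
columns showed no intraspecific variation, not the harder world where
they might. It also omits indels (appropriate for mtDNA coding regions),
phylogenetic rate structure, and base-composition bias; passing tests
therefore demonstrate the machinery, not robustness to those
complications.

`generate_flanked_template()` builds templates embedding the published
universal primer pairs at their canonical 5′-to-5′ spans (655 / 464 nt).
`synthetic_panel_references()` does the same per panel species using the
published panel primers and printed amplicon lengths. These are labelled
synthetic stand-ins for conspecific reference records: they let the
regression tests verify the engine, the length convention and panel
exclusivity offline, but they cannot detect a transcription error in the
published primer sequences themselves.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally and 1-based inclusive in
every user-facing report. Gaps disqualify consensus windows and primer
slices outright. Single-species alignments, unknown species labels, empty
call lists, sub-3-point dilution series and out-of-window product Tms all
raise early, named errors. Seeded generators save and restore the global
RNG state. Tm values are reported to 0.01 °C; panel search tie-breaks are
fully deterministic.

Problem sizes used throughout the test-suite and validation scripts —
4 species × 10–20 haplotypes, 655-column alignments, 20 generator seeds
for the melt-separation study — mirror the scale of the original
four-species study (40 sequenced individuals) while keeping every check
reproducible on a laptop.

## Known limitations

* No secondary-structure (hairpin) thermodynamics and no mismatch ΔG
  model; dimer screening is a 3′-anchored complementarity-run heuristic.
* Database-wide exclusivity of diagnostic sites (against all published
  congeners) is the user's responsibility; the package only guarantees
  exclusivity within the supplied alignment.
* Product Tm uses a GC/length formula, not sequence-order-aware
  thermodynamics; predicted melt peaks are nominal positions, not
  fluorescence physics.
* Ct values are simulated from the standard-curve model only; polymerase
  kinetics, amplification bias and empirical dynamic ranges are out of
  scope.
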