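# Melting-temperature models. Primers: nearest-neighbor thermodynamics
# (SantaLucia 1998 unified dinucleotide parameters) with the Owczarzy 2004
# monovalent-salt correction. Long products: the empirical GC/length/salt
# formula. Printed Tm values in published primer tables come from unstated
# models and are treated as plausibility bands only, never exact targets.

# SantaLucia (1998) unified NN parameters, 1 M NaCl.
# dH kcal/mol, dS cal/(mol K); both orientations of each pair included.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)   # per G/C terminus
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)    # per A/T terminus
GAS_CONSTANT <- 1.987                  # cal/(mol K)

#' Thermodynamic configuration
#'
#' Concentrations are molar. `divalent_salt` is folded into an equivalent
#' monovalent concentration (the usual `120 * sqrt([Mg2+] mM)` rule) before
#' the salt correction. Every report produced by the package carries the
#' model identifiers so Tm provenance is never ambiguous.
#'
#' @param monovalent_salt Monovalent cation concentration, M (default 0.05).
#' @param divalent_salt Divalent cation concentration, M (default 0).
#' @param primer_conc Total primer strand concentration, M (default 5e-7).
#' @param nn_parameter_set Identifier of the dinucleotide parameter set.
#' @param salt_correction Identifier of the monovalent correction.
#' @param product_tm_model Identifier of the long-product formula.
#' @return A `thermo_config` list.
#' @export
thermo_config <- function(monovalent_salt = 0.05, divalent_salt = 0,
                          primer_conc = 5e-7,
                          nn_parameter_set = "santalucia1998",
                          salt_correction = "owczarzy2004",
                          product_tm_model = "empirical_gc_length_salt") {
  if (monovalent_salt <= 0 || primer_conc <= 0 || divalent_salt < 0) {
    abort("salt and primer concentrations must be positive")
  }
  structure(list(monovalent_salt = monovalent_salt,
                 divalent_salt = divalent_salt,
                 primer_conc = primer_conc,
                 nn_parameter_set = nn_parameter_set,
                 salt_correction = salt_correction,
                 product_tm_model = product_tm_model),
            class = "thermo_config")
}

#' @export
print.thermo_config <- function(x, ...) {
  cat(sprintf(
    "<thermo_config> %s + %s | product: %s | Na+ %g M, Mg2+ %g M, primer %g M\n",
    x$nn_parameter_set, x$salt_correction, x$product_tm_model,
    x$monovalent_salt, x$divalent_salt, x$primer_conc))
  invisible(x)
}

effective_monovalent <- function(cfg) {
  na_mM <- cfg$monovalent_salt * 1000
  if (cfg$divalent_salt > 0) {
    na_mM <- na_mM + 120 * sqrt(cfg$divalent_salt * 1000)
  }
  na_mM / 1000
}

# NN Tm of one concrete A/C/G/T sequence (Kelvin at 1 M Na+, then
# Owczarzy 2004 correction to the configured monovalent concentration).
nn_tm_concrete <- function(seq, cfg) {
  b <- seq_chars(seq)
  n <- length(b)
  dinuc <- paste0(b[-n], b[-1])
  dH <- sum(NN_DH[dinuc])
  dS <- sum(NN_DS[dinuc])
  for (e in b[c(1L, n)]) {
    init <- if (e %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  # non-self-complementary duplex: CT/4
  tm1m <- dH * 1000 / (dS + GAS_CONSTANT * log(cfg$primer_conc / 4))
  na <- effective_monovalent(cfg)
  fgc <- mean(b %in% c("G", "C"))
  1 / (1 / tm1m + (4.29 * fgc - 3.95) * 1e-5 * log(na) +
         9.40e-6 * log(na)^2) - 273.15
}

#' Primer melting temperature (nearest-neighbor)
#'
#' Degenerate primers are scored as the mean Tm over their concrete
#' expansions (at most 64, else an error); [primer_tm_detail()] also reports
#' the conservative minimum.
#'
#' @param seq IUPAC primer sequence(s), length >= 8 nt, no gaps.
#' @param cfg A [thermo_config()].
#' @return Numeric Tm in deg C, one per input sequence.
#' @export
#' @examples
#' primer_tm("TTCGGGGGAAAGCCATATCG")
primer_tm <- function(seq, cfg = thermo_config()) {
  vapply(seq, function(s) nn_tm_stats(s, cfg)[["mean"]], 0,
         USE.NAMES = FALSE)
}

# fast path shared by primer_tm / primer_tm_detail: c(mean, min, max, n)
nn_tm_stats <- function(seq, cfg) {
  seq <- normalize_seq(seq)
  assert_iupac(seq)
  if (str_length(seq) < 8L) abort("primer shorter than 8 nt; Tm undefined")
  exps <- expand_degenerate(seq, max_expansions = 64)
  tms <- vapply(exps, nn_tm_concrete, 0, cfg = cfg)
  c(mean = round(mean(tms), 2), min = round(min(tms), 2),
    max = round(max(tms), 2), n = length(exps))
}

#' @rdname primer_tm
#' @export
primer_tm_detail <- function(seq, cfg = thermo_config()) {
  st <- nn_tm_stats(seq, cfg)
  tibble(sequence = normalize_seq(seq), n_expansions = as.integer(st[["n"]]),
         tm_mean = st[["mean"]], tm_min = st[["min"]], tm_max = st[["max"]],
         model = paste(cfg$nn_parameter_set, cfg$salt_correction, sep = "+"))
}

#' Predicted melting temperature of a long PCR product
#'
#' Empirical duplex formula
#' `Tm = 81.5 + 16.6 log10(Na+) + 0.41 (%GC) - 675 / length`,
#' valid for products of 50 nt and up; shorter inputs are primer-sized and
#' belong to [primer_tm()]. Salt enters additively, so pairwise Tm
#' differences between products are salt-invariant.
#'
#' @param seq Product sequence (>= 50 nt); or `NULL` if `gc` and `length`
#'   are given directly.
#' @param cfg A [thermo_config()].
#' @param gc,length GC fraction and product length, used when `seq` is NULL.
#' @return Tm in deg C.
#' @export
product_tm <- function(seq = NULL, cfg = thermo_config(), gc = NULL,
                       length = NULL) {
  if (!is.null(seq)) {
    if (length(seq) > 1L) {
      return(vapply(seq, product_tm, 0, cfg = cfg, USE.NAMES = FALSE))
    }
    seq <- normalize_seq(seq)
    assert_iupac(seq)
    length <- str_length(seq)
    if (length < 50L) {
      abort("product shorter than 50 nt: use primer_tm() for oligos")
    }
    gc <- gc_content(seq)
  } else {
    if (is.null(gc) || is.null(length)) abort("need `seq` or `gc` + `length`")
    if (any(length < 50)) {
      abort("product shorter than 50 nt: use primer_tm() for oligos")
    }
  }
  na <- effective_monovalent(cfg)
  81.5 + 16.6 * log10(na) + 0.41 * (gc * 100) - 675 / length
}
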