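# Independent oracles: deliberately naive re-implementations, written
# against the definitions rather than the package internals, used to
# cross-check the production code paths.

# IUPAC base sets, restated independently
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# brute-force minimal covering code: try all 15 codes, keep supersets of
# the observed bases, pick the smallest (unique by IUPAC construction)
oracle_consensus_code <- function(bases) {
  obs <- unique(unlist(ORACLE_SETS[bases]))
  sup <- Filter(function(code) all(obs %in% ORACLE_SETS[[code]]),
                names(ORACLE_SETS))
  sizes <- vapply(ORACLE_SETS[sup], length, 0L)
  sup[which.min(sizes)]
}

# independent SantaLucia-1998 NN Tm with Owczarzy-2004 monovalent
# correction, written as a plain per-step loop
oracle_nn_tm <- function(seq, na = 0.05, conc = 5e-7) {
  dh_tab <- list(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
                 CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
                 GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
                 TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds_tab <- list(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
                 CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
                 GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
                 TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  b <- strsplit(seq, "")[[1]]
  dh <- 0
  ds <- 0
  for (i in seq_len(length(b) - 1)) {
    key <- paste0(b[i], b[i + 1])
    dh <- dh + dh_tab[[key]]
    ds <- ds + ds_tab[[key]]
  }
  for (term in c(b[1], b[length(b)])) {
    if (term == "G" || term == "C") {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  tm1m <- dh * 1000 / (ds + 1.987 * log(conc / 4))
  fgc <- sum(b == "G" | b == "C") / length(b)
  1 / (1 / tm1m + (4.29 * fgc - 3.95) * 1e-5 * log(na) +
         9.40e-6 * log(na)^2) - 273.15
}

# position-by-position binding-site comparator (both strands)
oracle_binding_sites <- function(primer, template, exact3 = 3,
                                 max_internal = 2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  pch <- strsplit(primer, "")[[1]]
  tch <- strsplit(template, "")[[1]]
  L <- length(pch)
  n <- length(tch)
  hits <- list()
  matches <- function(code, base) base %in% ORACLE_SETS[[code]]
  for (s in seq_len(max(0, n - L + 1))) {
    # forward-acting
    mm <- 0; ok3 <- TRUE
    for (j in 1:L) {
      hit <- matches(pch[j], tch[s + j - 1])
      if (!hit) {
        if (j > L - exact3) ok3 <- FALSE else mm <- mm + 1
      }
    }
    if (ok3 && mm <= max_internal) {
      hits[[length(hits) + 1]] <- list(strand = "+", start = s - 1,
                                       mism = mm)
    }
    # reverse-acting: primer 3' base pairs at leftmost footprint position
    mm <- 0; ok3 <- TRUE
    for (j in 1:L) {
      # primer position j (5'->3') sits at template position s + L - j
      code <- comp[[pch[j]]]
      hit <- matches(code, tch[s + L - j])
      if (!hit) {
        if (j > L - exact3) ok3 <- FALSE else mm <- mm + 1
      }
    }
    if (ok3 && mm <= max_internal) {
      hits[[length(hits) + 1]] <- list(strand = "-", start = s - 1,
                                       mism = mm)
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(), start = integer(),
                      mism = integer()))
  }
  df <- do.call(rbind, lapply(hits, as.data.frame))
  df[order(df$start, df$strand), , drop = FALSE]
}

# exhaustive per-column strict diagnostic-site scan by set comparison
oracle_diag_sites <- function(mat, species, target) {
  tm <- mat[species == target, , drop = FALSE]
  om <- mat[species != target, , drop = FALSE]
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    u <- unique(tm[, j])
    if (length(u) != 1 || !u %in% c("A", "C", "G", "T")) next
    others <- unique(unlist(ORACLE_SETS[om[, j][om[, j] != "-"]]))
    if (!u %in% others) out <- c(out, j - 1L)
  }
  out
}

# exhaustive 3'-dimer run over all overlap offsets
oracle_dimer_run <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  can_pair <- function(x, y) {
    any(ORACLE_SETS[[x]] %in% comp[ORACLE_SETS[[y]]])
  }
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- 0
  for (k in seq_len(min(length(ac), length(bc)))) {
    run <- 0
    for (i in seq_len(k)) {
      if (can_pair(ac[length(ac) - k + i], bc[length(bc) - i + 1])) {
        run <- run + 1
        best <- max(best, run)
      } else run <- 0
    }
  }
  best
}

# exhaustive panel enumerator over all one-per-species combinations,
# restated from the acceptance rules
oracle_best_panel <- function(tabs, mode, min_spacing, min_dtm) {
  grids <- expand.grid(lapply(tabs, function(t) seq_len(nrow(t))))
  best <- NULL
  best_key <- c(-Inf, -Inf)
  for (r in seq_len(nrow(grids))) {
    sel <- as.integer(grids[r, ])
    lens <- mapply(function(t, i) t$exp_length[i], tabs, sel)
    tms <- mapply(function(t, i) t$exp_tm[i], tabs, sel)
    dl <- abs(outer(lens, lens, "-"))[upper.tri(diag(length(lens)))]
    dt <- abs(outer(tms, tms, "-"))[upper.tri(diag(length(tms)))]
    if (min(dl) < min_spacing) next
    if (mode == "melt" && min(dt) < min_dtm) next
    key <- c(min(dl), if (mode == "melt") min(dt) else 0)
    if (key[1] > best_key[1] + 1e-9 ||
        (abs(key[1] - best_key[1]) <= 1e-9 && key[2] > best_key[2] + 1e-9)) {
      best <- sel
      best_key <- key
    }
  }
  list(sel = best, key = best_key)
}

random_iupac <- function(n, codes = c("A", "C", "G", "T", "R", "Y", "S",
                                      "W", "K", "M", "N"),
                         weights = c(rep(10, 4), rep(1, 7))) {
  paste(sample(codes, n, replace = TRUE, prob = weights), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
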