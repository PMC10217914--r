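# Species-labeled alignments. A species_alignment is a tibble with columns
# id, species, sequence (all character), every sequence the same length.
# Columns are addressed 0-based half-open internally; all user-facing
# reports print 1-based inclusive coordinates.

new_species_alignment <- function(records) {
  structure(records, class = c("species_alignment", class(tibble())))
}

#' Build a species-labeled alignment
#'
#' @param id,species,sequence Character vectors of equal length; sequences
#'   must share one length (aligned) and use the IUPAC alphabet plus `-`.
#' @return A `species_alignment` tibble with columns id, species, sequence.
#' @export
species_alignment <- function(id, species, sequence) {
  recs <- tibble(id = as.character(id),
                 species = as.character(species),
                 sequence = unname(vapply(sequence, normalize_seq, "")))
  validate_species_alignment(new_species_alignment(recs))
}

validate_species_alignment <- function(aln) {
  if (nrow(aln) == 0L) abort("alignment has no records")
  if (anyNA(aln$species) || any(!nzchar(aln$species))) {
    abort("every record needs a species label")
  }
  lens <- str_length(aln$sequence)
  if (length(unique(lens)) != 1L) {
    abort(sprintf(
      "unaligned input: sequence lengths differ (%s)",
      paste(unique(lens), collapse = ", ")))
  }
  for (i in seq_len(nrow(aln))) {
    ch <- seq_chars(aln$sequence[i])
    bad <- which(!ch %in% c(IUPAC_CODES, "-"))
    if (length(bad)) {
      abort(sprintf("invalid character '%s' in record '%s' at column %d",
                    ch[bad[1]], aln$id[i], bad[1]))
    }
  }
  aln
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> %d records, %d columns, %d species\n",
              nrow(x), alignment_length(x), length(species_levels(x))))
  NextMethod()
}

#' Alignment length (number of columns)
#' @param aln A `species_alignment`.
#' @return Integer column count.
#' @export
alignment_length <- function(aln) {
  unique(str_length(aln$sequence))[1]
}

#' Species labels present in an alignment
#' @param aln A `species_alignment`.
#' @return Sorted character vector of species labels.
#' @export
species_levels <- function(aln) sort(unique(aln$species))

# character matrix, rows = records, columns = alignment columns
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Header-parsing rules for FASTA species labels
#'
#' `label_delim()` takes the `field`-th piece of the header after splitting
#' on `delim`; `label_regex()` takes capture group `group` of `pattern`.
#'
#' @param delim Delimiter string (fixed, not regex).
#' @param field 1-based field index holding the species label.
#' @return A function mapping a header string to a species label.
#' @export
label_delim <- function(delim = "|", field = 1L) {
  force(delim); force(field)
  function(header) {
    parts <- strsplit(header, delim, fixed = TRUE)[[1]]
    if (length(parts) < field) {
      abort(sprintf("header '%s' has no field %d under delimiter '%s'",
                    header, field, delim))
    }
    parts[field]
  }
}

#' @rdname label_delim
#' @param pattern Regular expression applied to the header.
#' @param group Capture group index (0 = whole match).
#' @export
label_regex <- function(pattern, group = 1L) {
  force(pattern); force(group)
  function(header) {
    m <- regmatches(header, regexec(pattern, header))[[1]]
    if (length(m) < group + 1L) {
      abort(sprintf("header '%s' does not match '%s'", header, pattern))
    }
    m[group + 1L]
  }
}

#' Read a species-labeled FASTA alignment
#'
#' Sequences are upper-cased and U is mapped to T. All records must share
#' one length; unequal lengths raise an "unaligned input" error. The species
#' label comes from the header via `label_rule`, unless `species_map` (a
#' data frame with columns id, species) overrides it.
#'
#' @param path FASTA file.
#' @param label_rule Function header -> species; see [label_delim()].
#' @param species_map Optional data frame id -> species overriding headers.
#' @return A `species_alignment`.
#' @export
read_species_alignment <- function(path, label_rule = label_delim("|", 1L),
                                   species_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- as.character(set)
  if (!is.null(species_map)) {
    sp <- setNames(as.character(species_map$species),
                   as.character(species_map$id))[ids]
    if (anyNA(sp)) {
      abort(sprintf("species_map is missing id '%s'", ids[which(is.na(sp))[1]]))
    }
  } else {
    sp <- vapply(ids, label_rule, "")
  }
  species_alignment(id = ids, species = sp, sequence = seqs)
}

#' Write a species-labeled alignment to FASTA
#'
#' Headers are the record ids verbatim, so a file written from an alignment
#' whose ids encode the species under the read-time `label_rule` round-trips
#' identically.
#'
#' @param aln A `species_alignment`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_species_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$sequence, aln$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Degenerate consensus of an alignment window
#'
#' Per column, the minimal IUPAC code covering every base observed in any
#' record (ambiguity codes in records are expanded first). A gap anywhere in
#' the window, or total degeneracy above `max_degeneracy`, rejects the
#' window; the result row then has `accepted = FALSE` and a reason.
#'
#' @param aln A `species_alignment`.
#' @param start,end 0-based half-open column window.
#' @param max_degeneracy Reject windows whose per-column expansion counts
#'   multiply beyond this.
#' @return One-row tibble: start, end, consensus, degeneracy, accepted,
#'   reason.
#' @export
consensus_with_degeneracy <- function(aln, start, end, max_degeneracy = Inf) {
  n <- alignment_length(aln)
  if (!(start >= 0 && start < end && end <= n)) {
    abort(sprintf("window [%d, %d) out of range for %d columns",
                  start, end, n))
  }
  m <- alignment_matrix(aln)[, (start + 1L):end, drop = FALSE]
  reject <- function(reason) {
    tibble(start = start, end = end, consensus = NA_character_,
           degeneracy = NA_real_, accepted = FALSE, reason = reason)
  }
  if (any(m == "-")) return(reject("gap in window"))
  codes <- apply(m, 2L, function(col) iupac_union_code(unique(col)))
  deg <- prod(lengths(IUPAC_SETS[codes]))
  if (deg > max_degeneracy) {
    return(reject(sprintf("degeneracy %d > %d", deg, max_degeneracy)))
  }
  tibble(start = start, end = end, consensus = paste(codes, collapse = ""),
         degeneracy = deg, accepted = TRUE, reason = NA_character_)
}

# Per-column consensus codes (NA where gapped) and per-column degeneracy
# across all records; O(columns) precomputation used by window scans.
column_codes <- function(m) {
  codes <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- unique(m[, j])
    codes[j] <- if ("-" %in% col) NA_character_ else iupac_union_code(col)
  }
  codes
}

#' Scan for conserved low-degeneracy windows
#'
#' Slides every window length in `len_range` across the alignment, keeping
#' gap-free windows whose consensus degeneracy stays at or below
#' `max_degeneracy`. These are the regions a common (consensus) primer is
#' drawn from.
#'
#' @param aln A `species_alignment`.
#' @param len_range Window lengths, `c(min, max)`.
#' @param max_degeneracy Degeneracy cap per window.
#' @return Tibble: start, end, consensus, degeneracy (0-based half-open),
#'   sorted by start then length.
#' @export
conserved_windows <- function(aln, len_range = c(18L, 25L),
                              max_degeneracy = 8) {
  m <- alignment_matrix(aln)
  codes <- column_codes(m)
  n <- length(codes)
  gap <- is.na(codes)
  degs <- rep(NA_real_, n)
  degs[!gap] <- lengths(IUPAC_SETS[codes[!gap]])
  # rolling products / gap counts via cumulative sums
  cum_log <- c(0, cumsum(ifelse(gap, 0, log(degs))))
  cum_gap <- c(0L, cumsum(gap))
  code_str <- paste(ifelse(gap, "!", codes), collapse = "")
  out <- vector("list", 0L)
  for (L in seq.int(len_range[1], len_range[2])) {
    if (L > n) break
    s <- 0:(n - L) # 0-based starts
    deg <- exp(cum_log[s + L + 1L] - cum_log[s + 1L])
    ngap <- cum_gap[s + L + 1L] - cum_gap[s + 1L]
    keep <- ngap == 0L & deg <= max_degeneracy + 1e-9
    if (!any(keep)) next
    s <- s[keep]
    out[[length(out) + 1L]] <- tibble(
      start = s, end = s + L,
      consensus = substring(code_str, s + 1L, s + L),
      degeneracy = round(deg[keep]))
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(),
                  consensus = character(), degeneracy = numeric()))
  }
  bind_rows(out) |> arrange(.data$start, .data$end)
}

#' Per-species consensus sequence
#'
#' @param aln A `species_alignment`.
#' @param species One species label from the alignment.
#' @param collapse `"degenerate"` gives the minimal IUPAC code per column;
#'   `"majority"` gives the most frequent concrete base (ties broken
#'   alphabetically), suitable as a concrete template.
#' @return A single sequence string (may contain `-` where all records gap).
#' @export
species_consensus <- function(aln, species,
                              collapse = c("degenerate", "majority")) {
  collapse <- match.arg(collapse)
  if (!species %in% aln$species) {
    abort(sprintf("species '%s' not in alignment", species))
  }
  m <- alignment_matrix(aln[aln$species == species, , drop = FALSE])
  codes <- apply(m, 2L, function(col) {
    u <- unique(col)
    if (collapse == "degenerate") {
      if ("-" %in% u) "-" else iupac_union_code(u)
    } else {
      bases <- unlist(IUPAC_SETS[col[col != "-"]], use.names = FALSE)
      if (!length(bases)) return("-")
      tt <- sort(table(bases), decreasing = TRUE)
      names(tt)[tt == max(tt)][1]
    }
  })
  paste(codes, collapse = "")
}
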