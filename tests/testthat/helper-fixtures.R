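# Shared in-code fixtures for the test suite.

toy_two_species <- function() {
  species_alignment(
    id = c("sp1|a", "sp1|b", "sp2|a", "sp2|b"),
    species = c("sp1", "sp1", "sp2", "sp2"),
    sequence = c("AAT", "AAT", "AAA", "AAA"))
}

# 2 species x 2 records with a conserved 5' block, one diagnostic column
# per species and a conserved 3' block, long enough to design primers on
toy_designable_alignment <- function(seed = 5, len = 300,
                                     anchors = c(120L, 205L)) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s1 <- s2 <- anc
  s1[anchors[1]] <- setdiff(c("A", "C", "G", "T"), anc[anchors[1]])[1]
  s2[anchors[2]] <- setdiff(c("A", "C", "G", "T"), anc[anchors[2]])[1]
  species_alignment(
    id = c("spA|1", "spA|2", "spB|1", "spB|2"),
    species = c("spA", "spA", "spB", "spB"),
    sequence = c(paste(s1, collapse = ""), paste(s1, collapse = ""),
                 paste(s2, collapse = ""), paste(s2, collapse = "")))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
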