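# Independent oracles used by the property tests. These deliberately
# re-derive expectations with simple brute-force code, separate from the
# package implementations they check.

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force construction of the ideal trace for a given zygosity over a
# short/long allele pair. For heterozygotes the primary channel carries the
# SHORT allele's base where the two alignments differ (the package builder
# uses the opposite convention, so agreement is not by construction).
oracle_trace <- function(short, long, zygosity) {
  s <- strsplit(short, "")[[1]]; l <- strsplit(long, "")[[1]]
  if (zygosity == "hom_short")
    return(list(primary = short, secondary = strrep("-", nchar(short))))
  if (zygosity == "hom_long")
    return(list(primary = long, secondary = strrep("-", nchar(long))))
  n <- length(l)
  p <- character(n); sec <- rep("-", n)
  for (i in seq_len(n)) {
    a <- if (i <= length(s)) s[i] else NA
    b <- l[i]
    if (is.na(a) || a == b) p[i] <- b
    else { p[i] <- a; sec[i] <- b }
  }
  list(primary = paste(p, collapse = ""), secondary = paste(sec, collapse = ""))
}

# random (short, long) pair: long = flank5 + block + suffix, short lacks the
# block. Rejection-sampled so that even the SHORT allele keeps >= 15
# evaluable positions after the (possibly right-shifted) divergence point;
# shorter reads are legitimately "insufficient" and tested separately.
oracle_indel_pair <- function() {
  repeat {
    f5 <- rand_bases(sample(5:20, 1))
    suf <- rand_bases(sample(16:30, 1))
    block <- rand_bases(sample(1:12, 1))
    short <- paste0(f5, suf); long <- paste0(f5, block, suf)
    s <- strsplit(short, "")[[1]]; l <- strsplit(long, "")[[1]]
    d <- length(s) + 1L
    for (i in seq_along(s)) if (s[i] != l[i]) { d <- i; break }
    if (length(s) - d + 1L >= 15) return(list(short = short, long = long))
  }
}

# Flat truth table for coat colour over locus-level genotypes, written
# independently of the cascade implementation.
oracle_colour <- function(E, K, A, B, D) {
  dd <- all(D == "d")
  rec <- sum(B != "B")
  shade <- if (rec >= 2) { if (dd) "isabella" else "brown" }
           else { if (dd) "blue" else "black" }
  if (all(E == "e")) return(if (dd) "pale_cream" else "red_yellow_cream")
  if (any(K == "K^B")) return(shade)
  rank <- c("A^y" = 1, "a^w" = 2, "a^t" = 3, "a" = 4)
  top <- names(rank)[min(rank[A])]
  if (top == "A^y") "fawn_sable" else if (top == "a^w") "agouti" else shade
}

# locus-level haplotype -> marker states (fixture construction for the
# decision-table tests)
locus_marker_states <- function(E, K, A, B, D) {
  hmap <- list(
    "e" = c(MC1R_306ter = "T", MC1R_M264V = "A"),
    "E" = c(MC1R_306ter = "C", MC1R_M264V = "A"),
    "E^m" = c(MC1R_306ter = "C", MC1R_M264V = "G"),
    "k^y" = c(CBD103_S54 = "GGG", CBD103_S53 = "G"),
    "K^B" = c(CBD103_S54 = "DelGGG", CBD103_S53 = "C"),
    "A^y" = c(ASIP_S82 = "T", ASIP_H83 = "A", ASIP_SINE = "no SINE", ASIP_R96 = "C"),
    "a^w" = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "no SINE", ASIP_R96 = "C"),
    "a^t" = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "SINE", ASIP_R96 = "C"),
    "a" = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "no SINE", ASIP_R96 = "T"),
    "B" = c(TYRP1_Q331ter = "C", TYRP1_345delP = "CCT"),
    "b^s" = c(TYRP1_Q331ter = "T", TYRP1_345delP = "CCT"),
    "b^d" = c(TYRP1_Q331ter = "C", TYRP1_345delP = "DelCCT"),
    "D" = c(`MLPH_157471_c.-22G>A` = "G"),
    "d" = c(`MLPH_157471_c.-22G>A` = "A")
  )
  states <- list()
  for (pair in list(E, K, A, B, D)) {
    h1 <- hmap[[pair[1]]]; h2 <- hmap[[pair[2]]]
    for (mid in names(h1)) states[[mid]] <- c(h1[[mid]], h2[[mid]])
  }
  states
}

# unordered pairs from an allele set
allele_pairs <- function(alleles) {
  out <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}

test_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) panel <<- load_panel()
    panel
  }
})

# shorthand: profile from locus-level coat genotypes over the base states
colour_profile <- function(panel, id, E, K, A, B, D) {
  states <- locus_marker_states(E, K, A, B, D)
  dogphen:::profile_from_states(panel, id, states,
                                base = dogphen:::base_states())
}
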