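# Synthetic cohort simulator.
#
# Genotypes are drawn under Hardy-Weinberg equilibrium, independently
# across loci. Multi-marker loci (E, K, A, B, S) are drawn as locus
# haplotypes and expanded deterministically into their marker states, so
# that the redundant markers of one locus stay mutually consistent; the
# single-marker traits are drawn per marker. T-Box G/G draws are rejected
# and resampled (the homozygous bobtail mutation is lethal), so configured
# frequencies are pre-selection frequencies.
#
# Phenotypes are produced by a "ground-truth twin" of the rule engine -- a
# separate vectorized implementation of the same biology -- plus the four
# documented exception channels that make real cohorts discordant:
# an untested TYRP1 brown allele (b^c) hidden behind a wild-type genotype
# call, breed-specific bobtails without the T-Box mutation, tail docking
# (observed tail not assessable), the unpredictable heterozygous ear
# marker, and a size misclassification channel for the single
# underpowered body-size marker.

# locus haplotype -> marker states
hap_states <- list(
  E = list("e"   = c(MC1R_306ter = "T", MC1R_M264V = "A"),
           "E"   = c(MC1R_306ter = "C", MC1R_M264V = "A"),
           "E^m" = c(MC1R_306ter = "C", MC1R_M264V = "G")),
  K = list("k^y" = c(CBD103_S54 = "GGG", CBD103_S53 = "G"),
           "K^B" = c(CBD103_S54 = "DelGGG", CBD103_S53 = "C")),
  A = list("A^y" = c(ASIP_S82 = "T", ASIP_H83 = "A", ASIP_SINE = "no SINE", ASIP_R96 = "C"),
           "a^w" = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "no SINE", ASIP_R96 = "C"),
           "a^t" = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "SINE", ASIP_R96 = "C"),
           "a"   = c(ASIP_S82 = "G", ASIP_H83 = "G", ASIP_SINE = "no SINE", ASIP_R96 = "T")),
  B = list("B"   = c(TYRP1_Q331ter = "C", TYRP1_345delP = "CCT"),
           "b^s" = c(TYRP1_Q331ter = "T", TYRP1_345delP = "CCT"),
           "b^d" = c(TYRP1_Q331ter = "C", TYRP1_345delP = "DelCCT")),
  D = list("D" = c(`MLPH_157471_c.-22G>A` = "G"),
           "d" = c(`MLPH_157471_c.-22G>A` = "A")),
  S = list("S"   = c(MITF_SNP = "A", MITF_INS = "no SINE"),
           "S^p" = c(MITF_SNP = "G", MITF_INS = "SINE")),
  M = list("M" = c(PMEL = "SINE"), "m" = c(PMEL = "no SINE")),
  H = list("H" = c(PSMB7 = "G"), "h" = c(PSMB7 = "T"))
)

single_markers <- c("FGF5", "RSPO2", "KRT71", "T-Box_C295G",
                    "BICFPJ1062878", "IGF1R")

#' Default allele frequencies for the simulator
#'
#' Per-locus haplotype frequencies for the multi-marker coat loci and
#' per-marker allele frequencies for the single-marker traits, chosen as
#' plausible values for a mixed European companion-dog population (the
#' bobtail mutation and merle/harlequin alleles rare, spotting and brown
#' alleles common). They are the fixed simulation conditions, not tuning
#' knobs.
#'
#' @return Named list of named numeric vectors, each summing to 1.
#' @export
default_allele_freqs <- function() {
  list(
    E = c("E^m" = 0.15, "E" = 0.55, "e" = 0.30),
    K = c("K^B" = 0.25, "k^y" = 0.75),
    A = c("A^y" = 0.35, "a^w" = 0.10, "a^t" = 0.40, "a" = 0.15),
    B = c("B" = 0.70, "b^s" = 0.20, "b^d" = 0.10),
    D = c("D" = 0.80, "d" = 0.20),
    S = c("S" = 0.65, "S^p" = 0.35),
    M = c("M" = 0.05, "m" = 0.95),
    H = c("H" = 0.03, "h" = 0.97),
    FGF5 = c("G" = 0.50, "T" = 0.50),
    RSPO2 = c("Ins" = 0.30, "noIns" = 0.70),
    KRT71 = c("A" = 0.60, "G" = 0.40),
    `T-Box_C295G` = c("G" = 0.10, "C" = 0.90),
    BICFPJ1062878 = c("G" = 0.50, "A" = 0.50),
    IGF1R = c("G" = 0.60, "A" = 0.40)
  )
}

#' Simulation configuration
#'
#' @param n_samples Number of dogs to simulate.
#' @param allele_freqs See [default_allele_freqs()]; each vector must sum
#'   to 1 (tolerance 1e-9).
#' @param exception_rates Named list of the discordance-channel
#'   probabilities: `p_bc` (a wild-type TYRP1 haplotype secretly carries
#'   the untested brown allele b^c), `p_ancestral_bobtail` (a long-tail
#'   genotype is phenotypically bobtailed via a non-T-Box mechanism),
#'   `p_docked` (a genetically long tail was cropped, making the
#'   observation not assessable), `p_ear_drop_given_het` (a heterozygous
#'   ear-marker dog shows drop ears), `p_size_misclass` (observed size
#'   class contradicts IGF1R).
#' @param seed Mandatory random seed.
#' @return A `dog_simconfig`.
#' @export
sim_config <- function(n_samples,
                       allele_freqs = default_allele_freqs(),
                       exception_rates = list(),
                       seed) {
  if (missing(seed)) stop_dogphen("sim_config requires an explicit seed")
  rates <- list(p_bc = 0.05, p_ancestral_bobtail = 0.10, p_docked = 0.05,
                p_ear_drop_given_het = 0.50, p_size_misclass = 0.30)
  bad <- setdiff(names(exception_rates), names(rates))
  if (length(bad)) stop_dogphen("unknown exception rate(s): ", paste(bad, collapse = ", "))
  rates[names(exception_rates)] <- exception_rates
  for (nm in names(rates)) {
    p <- rates[[nm]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_dogphen("exception rate ", nm, " must be a probability in [0,1]")
  }
  defaults <- default_allele_freqs()
  for (nm in names(defaults))
    if (is.null(allele_freqs[[nm]])) allele_freqs[[nm]] <- defaults[[nm]]
  for (nm in names(allele_freqs)) {
    f <- allele_freqs[[nm]]
    if (abs(sum(f) - 1) > 1e-9)
      stop_dogphen("allele frequencies for ", nm, " sum to ", sum(f), ", not 1")
    if (any(f < 0)) stop_dogphen("negative allele frequency for ", nm)
  }
  structure(list(n_samples = as.integer(n_samples),
                 allele_freqs = allele_freqs,
                 exception_rates = rates, seed = as.integer(seed)),
            class = "dog_simconfig")
}

#' Simulate a genotype/phenotype cohort
#'
#' Draws `n_samples` dogs under Hardy-Weinberg equilibrium at the
#' configured frequencies (loci independent; lethal T-Box G/G draws are
#' rejected and resampled), then generates observed phenotypes by a
#' vectorized ground-truth twin of the rule engine plus the configured
#' exception channels. Same seed, same cohort, byte for byte.
#'
#' @param config A `dog_simconfig`.
#' @param panel A `dog_panel`.
#' @return A `dog_cohort`: list with `profiles` (list of `dog_profile`),
#'   `phenotypes` (long data frame), `hidden_factors` (per-sample record of
#'   which exception channels fired) and `config`.
#' @export
simulate_cohort <- function(config, panel = load_panel()) {
  stopifnot(inherits(config, "dog_simconfig"))
  set.seed(config$seed)
  n <- config$n_samples
  fr <- config$allele_freqs
  rt <- config$exception_rates
  draw <- function(freqs) matrix(sample(names(freqs), 2 * n, replace = TRUE,
                                        prob = freqs), ncol = 2)
  hap <- lapply(fr, draw)

  # lethality: reject and resample homozygous bobtail draws
  tb <- hap[["T-Box_C295G"]]
  repeat {
    gg <- tb[, 1] == "G" & tb[, 2] == "G"
    if (!any(gg)) break
    tb[gg, ] <- matrix(sample(names(fr[["T-Box_C295G"]]), 2 * sum(gg),
                              replace = TRUE, prob = fr[["T-Box_C295G"]]),
                       ncol = 2)
  }
  hap[["T-Box_C295G"]] <- tb

  # hidden b^c: wild-type B haplotypes that secretly carry the untested allele
  bc <- matrix(FALSE, n, 2)
  for (j in 1:2) {
    wt <- hap$B[, j] == "B"
    bc[wt, j] <- rbinom(sum(wt), 1, rt$p_bc) == 1
  }

  sids <- sprintf("SIM%05d", seq_len(n))
  profiles <- vector("list", n)
  marker_ids <- names(panel$markers)
  for (i in seq_len(n)) {
    states <- list()
    for (loc in names(hap_states)) {
      key <- if (loc %in% names(fr)) loc else next
      h1 <- hap_states[[loc]][[hap[[loc]][i, 1]]]
      h2 <- hap_states[[loc]][[hap[[loc]][i, 2]]]
      for (mid in names(h1)) states[[mid]] <- c(h1[[mid]], h2[[mid]])
    }
    for (mid in single_markers) {
      al <- hap[[mid]][i, ]
      m <- panel$markers[[mid]]
      states[[mid]] <- m$alleles$state[match(al, m$alleles$name)]
    }
    profiles[[i]] <- profile_from_states(panel, sids[i], states)
  }

  truth <- twin_phenotypes(hap, bc, n, rt)
  phen <- truth$phenotypes
  phen$sample_id <- sids[phen$row]
  phen <- phen[, c("sample_id", "trait", "value", "assessable", "note")]
  hf <- truth$hidden
  hf$sample_id <- sids
  hf <- hf[, c("sample_id", setdiff(names(hf), "sample_id"))]

  structure(list(profiles = profiles, phenotypes = phen,
                 hidden_factors = hf, config = config),
            class = "dog_cohort")
}

# vectorized ground-truth phenotype generator (independent of the engine)
twin_phenotypes <- function(hap, bc, n, rt) {
  a_rank <- c("A^y" = 1, "a^w" = 2, "a^t" = 3, "a" = 4)
  ee <- hap$E[, 1] == "e" & hap$E[, 2] == "e"
  kb <- hap$K[, 1] == "K^B" | hap$K[, 2] == "K^B"
  aexp <- names(a_rank)[pmin(a_rank[hap$A[, 1]], a_rank[hap$A[, 2]])]
  rec <- (hap$B[, 1] != "B" | bc[, 1]) + (hap$B[, 2] != "B" | bc[, 2])
  brown <- rec >= 2
  dd <- hap$D[, 1] == "d" & hap$D[, 2] == "d"
  shade <- ifelse(brown, ifelse(dd, "isabella", "brown"),
                  ifelse(dd, "blue", "black"))
  colour <- ifelse(ee, ifelse(dd, "pale_cream", "red_yellow_cream"),
            ifelse(kb, shade,
            ifelse(aexp == "A^y", "fawn_sable",
            ifelse(aexp == "a^w", "agouti", shade))))

  n_sp <- (hap$S[, 1] == "S^p") + (hap$S[, 2] == "S^p")
  spotting <- c("minimal_white", "pseudo_irish", "piebald")[n_sp + 1]
  n_m <- (hap$M[, 1] == "M") + (hap$M[, 2] == "M")
  h_present <- hap$H[, 1] == "H" | hap$H[, 2] == "H"
  tan <- !ee & !kb & aexp == "a^t"
  pattern <- vapply(seq_len(n), function(i) {
    merle <- if (n_m[i] == 0 || ee[i]) "none" else if (n_m[i] == 1) "merle" else "mainly_white"
    compose_pattern(tan[i], spotting[i], merle, merle == "merle" && h_present[i])
  }, "")

  len <- ifelse(hap$FGF5[, 1] == "G" | hap$FGF5[, 2] == "G", "short", "long")
  n_curl <- (hap$KRT71[, 1] == "G") + (hap$KRT71[, 2] == "G")
  curl <- c("smooth", "wavy", "curly")[n_curl + 1]
  furn <- ifelse(hap$RSPO2[, 1] == "Ins" | hap$RSPO2[, 2] == "Ins",
                 "furnishings", "no_furnishings")
  structure_ <- paste(len, curl, furn, sep = "+")

  tb_het <- hap[["T-Box_C295G"]][, 1] == "G" | hap[["T-Box_C295G"]][, 2] == "G"
  genetic_tail <- ifelse(tb_het, "bobtail", "long_tail")
  ancestral <- !tb_het & rbinom(n, 1, rt$p_ancestral_bobtail) == 1
  docked <- !tb_het & !ancestral & rbinom(n, 1, rt$p_docked) == 1
  tail_val <- ifelse(ancestral, "bobtail", genetic_tail)

  ear_het <- hap$BICFPJ1062878[, 1] != hap$BICFPJ1062878[, 2]
  ear_hom_drop <- hap$BICFPJ1062878[, 1] == "A" & hap$BICFPJ1062878[, 2] == "A"
  het_drop <- rep(NA, n)
  het_drop[ear_het] <- rbinom(sum(ear_het), 1, rt$p_ear_drop_given_het) == 1
  ear <- ifelse(ear_het, ifelse(het_drop, "drop", "non_drop"),
                ifelse(ear_hom_drop, "drop", "non_drop"))

  small <- hap$IGF1R[, 1] == "A" | hap$IGF1R[, 2] == "A"
  size_flip <- rbinom(n, 1, rt$p_size_misclass) == 1
  size <- ifelse(xor(small, size_flip), "rather_small", "rather_tall")

  long_df <- function(trait, value, assessable = rep(TRUE, n),
                      note = rep("", n)) {
    data.frame(row = seq_len(n), trait = trait,
               value = ifelse(assessable, value, ""),
               assessable = assessable, note = note, stringsAsFactors = FALSE)
  }
  phenotypes <- rbind(
    long_df("coat_colour", colour),
    long_df("coat_pattern", pattern),
    long_df("coat_structure", structure_),
    long_df("tail_length", tail_val, assessable = !docked,
            note = ifelse(docked, "tail artificially docked", "")),
    long_df("ear_shape", ear),
    long_df("body_size", size)
  )
  hidden <- data.frame(
    n_hidden_bc = bc[, 1] + bc[, 2],
    bc_makes_brown = (bc[, 1] | bc[, 2]) &
      ((hap$B[, 1] != "B") + (hap$B[, 2] != "B") < 2) & rec >= 2,
    ancestral_bobtail = ancestral, docked = docked,
    ear_het = ear_het, ear_het_drop = het_drop, size_flipped = size_flip,
    stringsAsFactors = FALSE)
  list(phenotypes = phenotypes, hidden = hidden)
}
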