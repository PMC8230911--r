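# Deterministic validation cohorts.
#
# The published study does not deposit per-sample genotype tables; these
# cohorts are *reconstructions*: minimal genotypes consistent with the
# narrated cohort compositions, discordance counts and named samples
# (failed ASIP SINE sequencing with epistatic overrides, TYRP1-discordant
# brown dogs, breed-specific bobtails, the unreliable ear marker, the
# blind-test triple with identical genotypes except the ear marker). Each
# sample carries a short note describing the constraint it realizes.

base_states <- function() {
  list(
    "MC1R_306ter" = c("C", "C"), "MC1R_M264V" = c("A", "A"),
    "CBD103_S54" = c("GGG", "GGG"), "CBD103_S53" = c("G", "G"),
    "ASIP_S82" = c("G", "G"), "ASIP_H83" = c("G", "G"),
    "ASIP_SINE" = c("no SINE", "no SINE"), "ASIP_R96" = c("C", "C"),
    "TYRP1_Q331ter" = c("C", "C"), "TYRP1_345delP" = c("CCT", "CCT"),
    "MLPH_157471_c.-22G>A" = c("G", "G"),
    "MITF_SNP" = c("A", "A"), "MITF_INS" = c("no SINE", "no SINE"),
    "PMEL" = c("no SINE", "no SINE"), "PSMB7" = c("T", "T"),
    "FGF5" = c("G", "G"), "RSPO2" = c("no Ins", "no Ins"),
    "KRT71" = c("A", "A"), "T-Box_C295G" = c("C", "C"),
    "BICFPJ1062878" = c("G", "G"), "IGF1R" = c("G", "G")
  )
}

# common genotype shorthands (marker-state overrides)
.KB_KB <- list("CBD103_S54" = c("DelGGG", "DelGGG"), "CBD103_S53" = c("C", "C"))
.KB_ky <- list("CBD103_S54" = c("DelGGG", "GGG"), "CBD103_S53" = c("C", "G"))
.Ay_het <- list("ASIP_S82" = c("T", "G"), "ASIP_H83" = c("A", "G"))
.spot_het <- list("MITF_INS" = c("no SINE", "SINE"), "MITF_SNP" = c("A", "G"))
.spot_hom <- list("MITF_INS" = c("SINE", "SINE"), "MITF_SNP" = c("G", "G"))

ph_row <- function(sample_id, trait, value, assessable = TRUE, note = "") {
  data.frame(sample_id = sample_id, trait = trait,
             value = if (assessable) value else "",
             assessable = assessable, note = note, stringsAsFactors = FALSE)
}

make_cohort <- function(panel, dogs) {
  profiles <- list(); phen <- list(); notes <- list()
  for (d in dogs) {
    profiles[[length(profiles) + 1L]] <-
      profile_from_states(panel, d$id, d$states %||% list(), base = base_states())
    for (p in d$phen %||% list())
      phen[[length(phen) + 1L]] <- do.call(ph_row, c(list(d$id), p))
    notes[[length(notes) + 1L]] <- data.frame(
      sample_id = d$id, note = d$note %||% "", stringsAsFactors = FALSE)
  }
  list(profiles = profiles,
       phenotypes = if (length(phen)) do.call(rbind, phen) else NULL,
       notes = do.call(rbind, notes))
}

#' Deterministic validation cohorts
#'
#' Reconstructions of the published study cohorts: the 12-dog pilot set
#' (all markers called, with the three markers that showed only one allelic
#' state), the 16-dog coat-colour/pattern marker-test set (four
#' TYRP1-discordant brown dogs, three failed ASIP SINE calls rescued by
#' epistatic overrides, three K^B/k^y dogs without visible brindle, one dog
#' with both MITF markers failed), the 10-dog coat-structure, tail-length,
#' ear-shape and body-size marker-test sets with their narrated
#' discordances, and the 9-dog blind-test set with one triple of dogs
#' identical at every marker except the ear-shape marker.
#'
#' Genotypes not printed in the source narratives are minimal choices
#' consistent with them; each sample carries a paraphrased provenance note.
#'
#' @param panel A `dog_panel`.
#' @return Named list of cohorts (`pilot`, `coat_colour`,
#'   `coat_structure`, `tail_length`, `ear_shape`, `body_size`, `blind`),
#'   each a list with `profiles`, `phenotypes` (long data frame or `NULL`)
#'   and `notes`.
#' @export
validation_cohorts <- function(panel = load_panel()) {
  list(
    pilot = pilot_cohort(panel),
    coat_colour = coat_colour_cohort(panel),
    coat_structure = structure_cohort(panel),
    tail_length = tail_cohort(panel),
    ear_shape = ear_cohort(panel),
    body_size = size_cohort(panel),
    blind = blind_cohort(panel)
  )
}

pilot_cohort <- function(panel) {
  het_everything <- list(
    "MC1R_306ter" = c("C", "T"), "MC1R_M264V" = c("A", "G"),
    "CBD103_S54" = c("GGG", "DelGGG"), "CBD103_S53" = c("G", "C"),
    "ASIP_S82" = c("G", "T"), "ASIP_H83" = c("G", "A"),
    "ASIP_SINE" = c("no SINE", "SINE"), "ASIP_R96" = c("C", "T"),
    "TYRP1_Q331ter" = c("C", "T"), "TYRP1_345delP" = c("CCT", "DelCCT"),
    "MLPH_157471_c.-22G>A" = c("G", "A"),
    "MITF_SNP" = c("A", "G"), "MITF_INS" = c("no SINE", "SINE"),
    "FGF5" = c("G", "T"), "RSPO2" = c("no Ins", "Ins"),
    "KRT71" = c("A", "G"), "BICFPJ1062878" = c("G", "A"),
    "IGF1R" = c("G", "A"))
  hom_alt <- list(
    "MC1R_306ter" = c("T", "T"), "MC1R_M264V" = c("G", "G"),
    "CBD103_S54" = c("DelGGG", "DelGGG"), "CBD103_S53" = c("C", "C"),
    "ASIP_S82" = c("T", "T"), "ASIP_H83" = c("A", "A"),
    "ASIP_SINE" = c("SINE", "SINE"), "ASIP_R96" = c("T", "T"),
    "TYRP1_Q331ter" = c("T", "T"), "TYRP1_345delP" = c("DelCCT", "DelCCT"),
    "MLPH_157471_c.-22G>A" = c("A", "A"),
    "MITF_SNP" = c("G", "G"), "MITF_INS" = c("SINE", "SINE"),
    "FGF5" = c("T", "T"), "RSPO2" = c("Ins", "Ins"),
    "KRT71" = c("G", "G"), "BICFPJ1062878" = c("A", "A"),
    "IGF1R" = c("A", "A"))
  dogs <- c(
    list(list(id = "P01", note = "pilot: reference-state dog"),
         list(id = "P02", states = het_everything,
              note = "pilot: heterozygous at every polymorphic marker"),
         list(id = "P03", states = hom_alt,
              note = "pilot: homozygous alternate states; PMEL/PSMB7/T-Box stay single-state across the pilot")),
    lapply(4:12, function(i)
      list(id = sprintf("P%02d", i),
           states = if (i %% 2 == 0) list("FGF5" = c("G", "T")) else list("IGF1R" = c("G", "A")),
           note = "pilot: filler dog, fully genotyped"))
  )
  make_cohort(panel, dogs)
}

coat_colour_cohort <- function(panel) {
  cc <- function(colour, pattern, cnote = "", pnote = "") list(
    list("coat_colour", colour, TRUE, cnote),
    list("coat_pattern", pattern, TRUE, pnote))
  dogs <- list(
    list(id = "DE01_006",
         states = c(.KB_KB, list("ASIP_SINE" = NA, "TYRP1_Q331ter" = c("C", "T"))),
         phen = cc("brown", "minimal_white"),
         note = "solid brown; ASIP SINE sequencing failed but K^B/K^B overrides the A-locus; heterozygous b^s genotype calls black -> discordant (suspected untested brown allele)"),
    list(id = "DE01_052",
         states = c(.KB_KB, list("ASIP_SINE" = NA, "TYRP1_Q331ter" = c("C", "T"))),
         phen = cc("brown", "minimal_white"),
         note = "solid brown; same configuration as DE01_006 (failed ASIP SINE, K^B/K^B override, discordant TYRP1)"),
    list(id = "AT0282",
         states = list("ASIP_R96" = c("T", "T"), "TYRP1_Q331ter" = c("C", "T")),
         phen = cc("brown", "minimal_white"),
         note = "solid brown; recessive-black A genotype, heterozygous b^s calls black -> discordant"),
    list(id = "DE02_017",
         states = c(.KB_KB, .spot_hom),
         phen = cc("brown", "piebald"),
         note = "brown with white spotting; wild-type TYRP1 genotype calls black -> discordant (suspected untested brown allele on both haplotypes)"),
    list(id = "DE02_20",
         states = c(.spot_het,
                    list("MC1R_306ter" = c("T", "T"), "ASIP_SINE" = NA,
                         "TYRP1_Q331ter" = c("C", "T"))),
         phen = cc("red_yellow_cream", "pseudo_irish",
                   cnote = "clear fawn coat, recorded in the red/yellow/cream phaeomelanin class"),
         note = "fawn dog with white spotting; e/e makes the failed ASIP SINE call irrelevant; the e/e + B/b^s combination shows brown nose/eye rims (not predicted)"),
    list(id = "AT0134",
         states = c(.KB_KB, list("TYRP1_Q331ter" = c("T", "T"),
                                 "MITF_INS" = NA, "MITF_SNP" = NA)),
         phen = cc("brown", "minimal_white"),
         note = "solid brown, concordant; both MITF markers failed -> pattern not evaluable"),
    list(id = "AT0300",
         states = c(.KB_KB, list("TYRP1_Q331ter" = c("T", "T"))),
         phen = cc("brown", "minimal_white"),
         note = "solid brown, concordant (b^s/b^s)"),
    list(id = "AT0301",
         states = c(.KB_KB, .spot_hom,
                    list("TYRP1_345delP" = c("DelCCT", "DelCCT"))),
         phen = cc("brown", "piebald"),
         note = "brown with white spotting, concordant (b^d/b^d)"),
    list(id = "AT0183",
         states = c(.KB_ky, list("TYRP1_Q331ter" = c("C", "T"))),
         phen = cc("black", "minimal_white"),
         note = "solid black, concordant; K^B/k^y could be brindled but no brindle observed"),
    list(id = "AT0257",
         states = .KB_ky,
         phen = cc("black", "minimal_white"),
         note = "solid black, concordant; K^B/k^y could be brindled but no brindle observed"),
    list(id = "AT0062",
         states = c(.KB_ky, .spot_het),
         phen = cc("black", "pseudo_irish"),
         note = "black with white spotting, concordant; K^B/k^y could be brindled but no brindle observed"),
    list(id = "AT0302",
         states = c(.Ay_het, .spot_het),
         phen = cc("fawn_sable", "pseudo_irish"),
         note = "fawn/sable with white spotting, concordant"),
    list(id = "AT0303",
         phen = cc("agouti", "minimal_white"),
         note = "wild-type agouti, concordant"),
    list(id = "AT0304",
         states = c(.Ay_het, list("TYRP1_Q331ter" = c("T", "T"))),
         phen = cc("fawn_sable", "minimal_white",
                   cnote = "brown-shaded sable: sable with brown eumelanin tipping"),
         note = "brown sable, concordant as fawn/sable"),
    list(id = "AT0305",
         states = c(.KB_KB, list("PMEL" = c("SINE", "no SINE"))),
         phen = cc("black", "minimal_white+merle"),
         note = "black merle, concordant"),
    list(id = "AT0306",
         states = c(.KB_KB, list("MLPH_157471_c.-22G>A" = c("A", "A"),
                                 "TYRP1_Q331ter" = c("C", "T"))),
         phen = cc("blue", "minimal_white"),
         note = "blue (grey), concordant: heterozygous b^s with d/d dilution of black")
  )
  make_cohort(panel, dogs)
}

structure_cohort <- function(panel) {
  sdog <- function(id, states, value) list(
    id = id, states = states,
    phen = list(list("coat_structure", value)),
    note = "coat-structure marker test: concordant")
  dogs <- list(
    sdog("ST01", list("FGF5" = c("T", "T")), "long+smooth+no_furnishings"),
    sdog("ST02", list("FGF5" = c("G", "T")), "short+smooth+no_furnishings"),
    sdog("ST03", list("KRT71" = c("A", "G")), "short+wavy+no_furnishings"),
    sdog("ST04", list("KRT71" = c("G", "G")), "short+curly+no_furnishings"),
    sdog("ST05", list("RSPO2" = c("Ins", "no Ins")), "short+smooth+furnishings"),
    sdog("ST06", list("FGF5" = c("T", "T"), "KRT71" = c("G", "G"),
                      "RSPO2" = c("Ins", "Ins")), "long+curly+furnishings"),
    sdog("ST07", list("FGF5" = c("T", "T"), "KRT71" = c("A", "G")),
         "long+wavy+no_furnishings"),
    sdog("ST08", list(), "short+smooth+no_furnishings"),
    sdog("ST09", list("FGF5" = c("T", "T"), "RSPO2" = c("Ins", "no Ins")),
         "long+smooth+furnishings"),
    sdog("ST10", list("KRT71" = c("G", "G"), "RSPO2" = c("Ins", "no Ins")),
         "short+curly+furnishings")
  )
  make_cohort(panel, dogs)
}

tail_cohort <- function(panel) {
  dogs <- c(
    lapply(c("AT0056", "AT0062", "AT0210"), function(id) list(
      id = id, states = list(),
      phen = list(list("tail_length", "bobtail")),
      note = paste0(id, ": bobtailed breed without the T-Box mutation (long-tail genotype) -> discordant"))),
    lapply(c("TL01", "TL02"), function(id) list(
      id = id, states = list("T-Box_C295G" = c("G", "C")),
      phen = list(list("tail_length", "bobtail")),
      note = "heterozygous T-Box mutation, bobtail, concordant")),
    lapply(sprintf("TL%02d", 3:7), function(id) list(
      id = id, states = list(),
      phen = list(list("tail_length", "long_tail")),
      note = "long tail, concordant"))
  )
  make_cohort(panel, dogs)
}

ear_cohort <- function(panel) {
  dogs <- c(
    list(
      list(id = "AT0274", states = list("BICFPJ1062878" = NA),
           phen = list(list("ear_shape", "drop")),
           note = "ear marker yielded no sequence data -> not evaluable"),
      list(id = "EAR01", states = list(),
           phen = list(list("ear_shape", "non_drop")),
           note = "G/G non-drop, concordant"),
      list(id = "EAR02", states = list("BICFPJ1062878" = c("A", "A")),
           phen = list(list("ear_shape", "drop")),
           note = "A/A drop, concordant"),
      list(id = "EAR03", states = list("BICFPJ1062878" = c("A", "A")),
           phen = list(list("ear_shape", "non_drop")),
           note = "A/A but non-drop ears observed -> discordant")),
    lapply(1:6, function(i) list(
      id = sprintf("EH%02d", i),
      states = list("BICFPJ1062878" = c("G", "A")),
      phen = list(list("ear_shape", if (i <= 3) "drop" else "non_drop")),
      note = "heterozygous ear marker: no clear interpretation (three such dogs drop, three non-drop)"))
  )
  make_cohort(panel, dogs)
}

size_cohort <- function(panel) {
  szdog <- function(id, geno, obs, note) list(
    id = id, states = if (is.null(geno)) list() else list("IGF1R" = geno),
    phen = list(list("body_size", obs)), note = note)
  dogs <- list(
    szdog("SZ01", c("A", "A"), "rather_small", "A/A small, concordant"),
    szdog("SZ02", c("A", "A"), "rather_small", "A/A small, concordant"),
    szdog("SZ03", c("G", "A"), "rather_small", "A/G small, concordant"),
    szdog("SZ04", c("G", "A"), "rather_small", "A/G small, concordant"),
    szdog("SZ05", NULL, "rather_tall", "G/G tall, concordant"),
    szdog("SZ06", NULL, "rather_tall", "G/G tall, concordant"),
    szdog("SZ07", NULL, "rather_tall", "G/G tall, concordant"),
    szdog("SZ08", NULL, "rather_small", "G/G but small dog -> discordant"),
    szdog("SZ09", NULL, "rather_small", "G/G but small dog -> discordant"),
    szdog("SZ10", c("G", "A"), "rather_tall", "A/G but tall dog -> discordant")
  )
  make_cohort(panel, dogs)
}

blind_cohort <- function(panel) {
  tanpoint_core <- list("ASIP_SINE" = c("SINE", "SINE"), "FGF5" = c("T", "T"),
                        "BICFPJ1062878" = c("A", "A"))
  obs_tanpoint <- list(
    list("coat_colour", "black"),
    list("coat_pattern", "tan_points+minimal_white"),
    list("coat_structure", "long+smooth+no_furnishings"),
    list("tail_length", "long_tail"),
    list("ear_shape", "", FALSE, "ear shape not traceable on the photo documentation"),
    list("body_size", "rather_tall"))
  dogs <- list(
    list(id = "D4925",
         states = c(.KB_KB, list("TYRP1_Q331ter" = c("T", "T"),
                                 "FGF5" = c("G", "T"), "KRT71" = c("A", "G"),
                                 "RSPO2" = c("no Ins", "Ins"),
                                 "IGF1R" = c("G", "A"))),
         phen = list(
           list("coat_colour", "brown"), list("coat_pattern", "minimal_white"),
           list("coat_structure", "short+wavy+furnishings"),
           list("tail_length", "", FALSE, "tail appears artificially cropped"),
           list("ear_shape", "non_drop"), list("body_size", "rather_small")),
         note = "high concordance except the tail: long-tail genotype but the tail was cropped"),
    list(id = "D4926", states = tanpoint_core, phen = obs_tanpoint,
         note = "black-and-tan dog; genotype identical to D4928 (all markers) and D4931 (all but the ear marker)"),
    list(id = "D4927",
         states = c(tanpoint_core, list("MC1R_306ter" = c("C", "T"),
                                        "MC1R_M264V" = c("A", "G"))),
         phen = c(obs_tanpoint[-5],
                  list(list("ear_shape", "drop"))),
         note = "like the identical triple but heterozygous at both E-locus markers: black and tan with melanistic mask"),
    list(id = "D4928", states = tanpoint_core, phen = obs_tanpoint,
         note = "genotype identical to D4926; identical identikit"),
    list(id = "D4929",
         states = list("MC1R_306ter" = c("T", "T"), "IGF1R" = c("A", "A")),
         phen = list(
           list("coat_colour", "red_yellow_cream"), list("coat_pattern", "minimal_white"),
           list("coat_structure", "short+smooth+no_furnishings"),
           list("tail_length", "long_tail"), list("ear_shape", "non_drop"),
           list("body_size", "rather_small")),
         note = "light-coloured dog with upright ears; fully concordant"),
    list(id = "D4930",
         states = c(.KB_KB, .spot_het,
                    list("FGF5" = c("T", "T"), "KRT71" = c("G", "G"),
                         "T-Box_C295G" = c("G", "C"),
                         "BICFPJ1062878" = c("G", "A"))),
         phen = list(
           list("coat_colour", "black"), list("coat_pattern", "pseudo_irish"),
           list("coat_structure", "long+curly+no_furnishings"),
           list("tail_length", "bobtail"), list("ear_shape", "drop"),
           list("body_size", "rather_small")),
         note = "concordant in all but two markers: size marker suggests tall but the dog is small; heterozygous ear marker is inconclusive"),
    list(id = "D4931",
         states = c(tanpoint_core["ASIP_SINE"], tanpoint_core["FGF5"],
                    list("BICFPJ1062878" = c("G", "A"))),
         phen = obs_tanpoint,
         note = "identical to D4926/D4928 at every marker except the heterozygous ear-shape marker"),
    list(id = "D4933",
         states = c(.KB_ky, .spot_hom, list("FGF5" = c("G", "T"))),
         phen = list(
           list("coat_colour", "black"), list("coat_pattern", "piebald"),
           list("coat_structure", "short+smooth+no_furnishings"),
           list("tail_length", "long_tail"),
           list("ear_shape", "", FALSE, "non-drop ears could not be unambiguously assessed from the photo"),
           list("body_size", "rather_tall")),
         note = "five of six traits predicted; K^B/k^y could be brindled but the dog is black with white spotting"),
    list(id = "D4934",
         states = c(.Ay_het,
                    list("FGF5" = c("T", "T"), "KRT71" = c("A", "G"),
                         "RSPO2" = c("Ins", "Ins"), "T-Box_C295G" = c("G", "C"),
                         "BICFPJ1062878" = c("G", "A"), "IGF1R" = c("G", "A"))),
         phen = list(
           list("coat_colour", "fawn_sable"), list("coat_pattern", "minimal_white"),
           list("coat_structure", "long+wavy+furnishings"),
           list("tail_length", "long_tail"), list("ear_shape", "drop"),
           list("body_size", "rather_tall")),
         note = "coat traits concordant; tail and size discrepant, heterozygous ear marker inconclusive")
  )
  make_cohort(panel, dogs)
}
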