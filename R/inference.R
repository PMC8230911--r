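# The genotype -> phenotype rule engine.
#
# Coat colour and pattern follow the classical locus hierarchy: MC1R
# (E-locus) is epistatic to the K- and A-loci -- an e/e dog produces only
# phaeomelanin (red/yellow/cream) whatever its K and A genotypes; otherwise
# a dominant K^B allele (CBD103) forces solid eumelanin and masks the
# A-locus; only a k^y/k^y dog expresses ASIP, whose alleles rank
# A^y (fawn/sable) > a^w (agouti) > a^t (tan points) > a (recessive black).
# TYRP1 (B) renders eumelanin brown when two recessive alleles are present
# in any combination across its two markers; MLPH (D) dilutes both pigments
# when homozygous d/d; MITF (S), PMEL (M) and PSMB7 (H) modify the pattern.
#
# Missing genotypes are handled by enumerating the completions a missing
# locus could take: when every completion yields the same value the
# prediction is still `determined` (the epistatic override is then named in
# the derivation chain), otherwise the finite value set is reported as
# `ambiguous`.

new_locus_state <- function(locus, genotype = NULL, expressed = NA_character_,
                            candidates = character(0), basis = character(0),
                            conflict = FALSE, missing = FALSE,
                            relevance = "relevant", note = character(0),
                            detail = list()) {
  structure(list(locus = locus, genotype = genotype, expressed = expressed,
                 candidates = candidates, basis = basis, conflict = conflict,
                 missing = missing, relevance = relevance, note = note,
                 detail = detail),
            class = "dog_locus_state")
}

#' Reconstruct the genotype of one coat-colour locus from its markers
#'
#' Applies the per-locus reconstruction rules: E from MC1R_306ter (e
#' dosage) and MC1R_M264V (E^m assigned to the non-e dosage, since phase
#' between the two SNPs is unrecoverable from Sanger data); K from the two
#' CBD103 markers jointly, with disagreement flagged as a conflict; A from
#' the four ASIP markers by the unphased dominance shortcut (the top-ranked
#' allele whose presence is provable is expressed; combinations that remain
#' ambiguous report candidate alleles rather than guessing); B as the
#' recessive-allele count across the two TYRP1 markers (assuming the two
#' variants never share a haplotype); D, S, M, H directly from their single
#' markers, S cross-checked against MITF_SNP (the SINE call wins on
#' disagreement, which sets the conflict flag).
#'
#' @param profile A `dog_profile`.
#' @param locus One of `"E","K","A","B","D","S","M","H"`.
#' @param panel A `dog_panel`.
#' @return A `dog_locus_state` with the reconstructed genotype (when
#'   derivable), the expressed allele or candidate set, the marker basis,
#'   and conflict/missing flags. Conflicts and gaps are states, not errors.
#' @export
reconstruct_locus <- function(profile, locus, panel) {
  switch(locus,
    E = reconstruct_E(profile),
    K = reconstruct_K(profile),
    A = reconstruct_A(profile),
    B = reconstruct_B(profile),
    D = reconstruct_single(profile, "D", "MLPH_157471_c.-22G>A", "d",
                           function(n) list(dd = n == 2)),
    S = reconstruct_S(profile),
    M = reconstruct_single(profile, "M", "PMEL", "M",
                           function(n) list(n_M = n)),
    H = reconstruct_single(profile, "H", "PSMB7", "H",
                           function(n) list(n_H = n)),
    stop_dogphen("unknown locus: ", locus)
  )
}

reconstruct_E <- function(profile) {
  n_e <- allele_count(profile, "MC1R_306ter", "e")
  basis <- c("MC1R_306ter", "MC1R_M264V")
  if (is.na(n_e))
    return(new_locus_state("E", missing = TRUE, basis = basis,
                           note = "MC1R_306ter missing: e dosage unknown",
                           detail = list(ee = NA, mask = NA)))
  n_em_raw <- allele_count(profile, "MC1R_M264V", "E^m")
  note <- character(0)
  if (is.na(n_em_raw)) {
    geno <- c(rep("e", n_e), rep("E", 2 - n_e))
    mask <- if (n_e == 2) FALSE else NA
    if (n_e < 2) note <- "MC1R_M264V missing: melanistic-mask status unknown"
    n_em <- 0L
  } else {
    n_em <- min(n_em_raw, 2L - n_e)
    if (n_em_raw > 2L - n_e)
      note <- "E^m dosage exceeds non-e dosage; E^m assigned to non-e haplotypes (unphased shortcut)"
    geno <- c(rep("e", n_e), rep("E^m", n_em),
              rep("E", 2 - n_e - n_em))
    mask <- n_em >= 1
  }
  expressed <- if (n_e == 2) "e" else if (isTRUE(n_em >= 1)) "E^m" else "E"
  new_locus_state("E", genotype = sort(geno), expressed = expressed,
                  basis = basis, note = note,
                  detail = list(ee = n_e == 2, mask = mask))
}

reconstruct_K <- function(profile) {
  basis <- c("CBD103_S54", "CBD103_S53")
  n54 <- allele_count(profile, "CBD103_S54", "K^B")
  n53 <- allele_count(profile, "CBD103_S53", "K^B")
  if (is.na(n54) && is.na(n53))
    return(new_locus_state("K", missing = TRUE, basis = basis,
                           detail = list(kb_present = NA, het = NA)))
  conflict <- !is.na(n54) && !is.na(n53) && n54 != n53
  n <- if (!is.na(n54)) n54 else n53  # the microINDEL marker wins on conflict
  geno <- sort(c(rep("K^B", n), rep("k^y", 2 - n)))
  new_locus_state("K", genotype = geno,
                  expressed = if (n >= 1) "K^B" else "k^y",
                  basis = basis, conflict = conflict,
                  note = if (conflict) "CBD103_S54 and CBD103_S53 disagree; microINDEL call used" else character(0),
                  detail = list(kb_present = n >= 1, het = n == 1))
}

reconstruct_A <- function(profile) {
  basis <- c("ASIP_S82", "ASIP_H83", "ASIP_SINE", "ASIP_R96")
  n82 <- allele_count(profile, "ASIP_S82", "A^y")
  n83 <- allele_count(profile, "ASIP_H83", "A^y")
  n_at <- allele_count(profile, "ASIP_SINE", "a^t")
  n_a <- allele_count(profile, "ASIP_R96", "a")
  if (all(is.na(c(n82, n83, n_at, n_a))))
    return(new_locus_state("A", missing = TRUE, basis = basis))

  ay_known <- !is.na(n82) || !is.na(n83)
  ay_present <- isTRUE(n82 >= 1) || isTRUE(n83 >= 1)
  n_ay <- max(c(n82, n83), na.rm = !all(is.na(c(n82, n83))))

  conflict <- FALSE
  note <- character(0)
  if (ay_present) {
    expressed <- "A^y"; candidates <- "A^y"
  } else {
    # A^y absent (or unknowable); rank the provable alleles a^w > a^t > a
    base <- if (!is.na(n_at) && !is.na(n_a)) {
      tot <- n_at + n_a
      if (tot > 2) { conflict <- TRUE
        note <- "more recessive A alleles than haplotypes; a^t and a assumed never on one haplotype"
        if (n_at >= 1) "a^t" else "a"
      } else if (tot < 2) "a^w"
      else if (n_at >= 1) "a^t" else "a"
    } else if (is.na(n_at) && !is.na(n_a)) {
      if (n_a == 2) "a" else c("a^w", "a^t")
    } else if (!is.na(n_at) && is.na(n_a)) {
      if (n_at == 2) "a^t" else if (n_at == 1) c("a^w", "a^t") else c("a^w", "a")
    } else c("a^w", "a^t", "a")
    candidates <- if (!ay_known) unique(c("A^y", base)) else base
    expressed <- if (length(candidates) == 1) candidates else NA_character_
  }

  geno <- NULL
  if (!anyNA(c(n82, n83, n_at, n_a))) {
    n_aw <- 2 - n_ay - n_at - n_a
    if (n_aw < 0) { conflict <- TRUE } else {
      geno <- sort(c(rep("A^y", n_ay), rep("a^w", n_aw),
                     rep("a^t", n_at), rep("a", n_a)))
    }
  }
  new_locus_state("A", genotype = geno, expressed = expressed,
                  candidates = candidates, basis = basis, conflict = conflict,
                  missing = anyNA(c(n82, n83, n_at, n_a)), note = note,
                  detail = list(ambiguous = length(candidates) > 1))
}

reconstruct_B <- function(profile) {
  basis <- c("TYRP1_Q331ter", "TYRP1_345delP")
  n_bs <- allele_count(profile, "TYRP1_Q331ter", "b^s")
  n_bd <- allele_count(profile, "TYRP1_345delP", "b^d")
  if (is.na(n_bs) && is.na(n_bd))
    return(new_locus_state("B", missing = TRUE, basis = basis,
                           detail = list(complete = FALSE, rec_known = 0L)))
  complete <- !anyNA(c(n_bs, n_bd))
  rec_known <- sum(c(n_bs, n_bd), na.rm = TRUE)
  conflict <- FALSE
  geno <- NULL
  note <- "brown requires two recessive TYRP1 alleles in any combination; b^s and b^d assumed never on one haplotype"
  if (complete) {
    if (rec_known > 2) conflict <- TRUE
    else geno <- sort(c(rep("b^s", n_bs), rep("b^d", n_bd),
                        rep("B", 2 - rec_known)))
  }
  new_locus_state("B", genotype = geno,
                  expressed = if (complete || rec_known >= 2)
                    (if (rec_known >= 2) "b" else "B") else NA_character_,
                  basis = basis, conflict = conflict,
                  missing = !complete, note = note,
                  detail = list(complete = complete, rec_known = rec_known,
                                brown = if (complete || rec_known >= 2) rec_known >= 2 else NA))
}

reconstruct_single <- function(profile, locus, marker_id, counted_allele, detail_fn) {
  n <- allele_count(profile, marker_id, counted_allele)
  if (is.na(n))
    return(new_locus_state(locus, missing = TRUE, basis = marker_id,
                           detail = detail_fn(NA_integer_)))
  call <- profile$calls[[marker_id]]
  new_locus_state(locus, genotype = call$alleles,
                  expressed = if (n >= 1) counted_allele else setdiff(call$alleles, counted_allele)[1] %||% call$alleles[1],
                  basis = marker_id, detail = detail_fn(n))
}

reconstruct_S <- function(profile) {
  basis <- c("MITF_INS", "MITF_SNP")
  n_sp <- allele_count(profile, "MITF_INS", "S^p")
  n_sp_snp <- allele_count(profile, "MITF_SNP", "S^p")
  if (is.na(n_sp)) {
    return(new_locus_state("S", missing = TRUE, basis = basis,
                           note = "MITF_INS missing; MITF_SNP alone is secondary evidence and is not called",
                           detail = list(n_sp = NA_integer_)))
  }
  conflict <- !is.na(n_sp_snp) && n_sp_snp != n_sp
  new_locus_state("S",
                  genotype = sort(c(rep("S^p", n_sp), rep("S", 2 - n_sp))),
                  expressed = c("S", "S/S^p", "S^p")[n_sp + 1],
                  basis = basis, conflict = conflict,
                  note = if (conflict) "MITF_SNP disagrees with MITF_INS; SINE call wins" else character(0),
                  detail = list(n_sp = n_sp))
}

# all eight coat loci, with the epistasis relevance pass applied
reconstruct_all <- function(profile, panel) {
  states <- setNames(
    lapply(c("E", "K", "A", "B", "D", "S", "M", "H"),
           function(l) reconstruct_locus(profile, l, panel)),
    c("E", "K", "A", "B", "D", "S", "M", "H"))
  if (isTRUE(states$E$detail$ee)) {
    states$K$relevance <- "overridden"
    states$A$relevance <- "overridden"
  } else if (isTRUE(states$K$detail$kb_present)) {
    states$A$relevance <- "overridden"
  }
  for (l in names(states))
    if (states[[l]]$missing && states[[l]]$relevance == "relevant")
      states[[l]]$relevance <- "not_evaluable"
  states
}

new_prediction <- function(trait, values = character(0),
                           certainty = c("determined", "ambiguous",
                                         "inconclusive", "not_evaluable"),
                           caveats = character(0), derivation = character(0),
                           qualifiers = character(0)) {
  certainty <- match.arg(certainty)
  if (certainty == "determined" && length(values) != 1)
    stop_dogphen("determined prediction must carry exactly one value")
  if (certainty == "not_evaluable" && length(values) != 0)
    stop_dogphen("not_evaluable prediction must carry no value")
  bad <- setdiff(caveats, caveat_codes())
  if (length(bad)) stop_dogphen("unknown caveat code(s): ", paste(bad, collapse = ", "))
  structure(list(trait = trait, values = values, certainty = certainty,
                 caveats = unique(caveats), derivation = derivation,
                 qualifiers = qualifiers),
            class = "dog_prediction")
}

eumelanin_shades <- c("black", "brown", "blue", "isabella")

shade_of <- function(brown, dd) {
  if (brown) { if (dd) "isabella" else "brown" } else { if (dd) "blue" else "black" }
}

# possible eumelanin shades given the B and D states (enumerating unknowns)
shade_set <- function(B, D) {
  brown_opts <- if (isTRUE(B$detail$complete)) B$detail$brown
                else if (B$detail$rec_known >= 2) TRUE else c(FALSE, TRUE)
  dd_opts <- if (D$missing) c(FALSE, TRUE) else D$detail$dd
  unique(unlist(lapply(brown_opts, function(b)
    vapply(dd_opts, function(dd) shade_of(b, dd), ""))))
}

#' Predict coat colour from reconstructed locus states
#'
#' Applies the dominance cascade: e/e fixes a phaeomelanin coat whatever K
#' and A carry; otherwise K^B forces a solid eumelanin coat and only
#' k^y/k^y expresses the A-locus (A^y fawn/sable > a^w agouti > a^t/a
#' eumelanin). The eumelanin shade comes from B (two recessive TYRP1
#' alleles in any combination give brown) and D (d/d dilutes black to blue
#' and brown to isabella; on an e/e coat d/d gives a pale-cream dilution).
#' Missing loci are enumerated: a unique outcome stays `determined` (with
#' the overriding locus named), otherwise the value set is `ambiguous`.
#' A B-locus reconstruction with fewer than two tested recessive alleles
#' carries the `untested_allele_bc` caveat: an untested rare brown allele
#' could make such a dog brown despite a black genotype call.
#'
#' @param states Named list of `dog_locus_state` from the reconstruction
#'   step (loci E, K, A, B, D at least).
#' @return A `dog_prediction` for `coat_colour`.
#' @export
predict_coat_colour <- function(states) {
  E <- states$E; K <- states$K; A <- states$A; B <- states$B; D <- states$D
  deriv <- character(0)
  if (E$missing)
    return(new_prediction("coat_colour", certainty = "not_evaluable",
                          derivation = c("E-locus not evaluable: MC1R_306ter missing",
                                         "e/e epistasis undecidable, no colour prediction")))
  caveats <- character(0)
  qualifiers <- character(0)

  if (E$detail$ee) {
    deriv <- c(deriv, "E: e/e -> phaeomelanin coat (red/yellow/cream); MC1R is epistatic to K and A",
               "K-locus overridden by E (e/e epistasis)",
               "A-locus overridden by E (e/e epistasis)")
    dd_opts <- if (D$missing) c(FALSE, TRUE) else D$detail$dd
    values <- unique(vapply(dd_opts, function(dd)
      if (dd) "pale_cream" else "red_yellow_cream", ""))
    if (!D$missing)
      deriv <- c(deriv, paste0("D: ", paste(D$genotype, collapse = "/"),
                               if (D$detail$dd) " -> phaeomelanin diluted (pale cream)" else " -> no dilution"))
    else deriv <- c(deriv, "D-locus missing: dilution of the phaeomelanin coat undecided")
  } else {
    if (isTRUE(E$detail$mask)) {
      qualifiers <- c(qualifiers, "melanistic_mask")
      deriv <- c(deriv, "E: E^m present -> melanistic mask")
    }
    shades <- shade_set(B, D)
    kb_opts <- if (K$missing) c(TRUE, FALSE) else K$detail$kb_present
    a_opts <- if (A$missing && length(A$candidates) == 0) c("A^y", "a^w", "a^t", "a")
              else if (!is.na(A$expressed)) A$expressed else A$candidates
    values <- character(0)
    for (kb in kb_opts) {
      if (kb) values <- c(values, shades)
      else for (a in a_opts) {
        values <- c(values,
                    if (a == "A^y") "fawn_sable"
                    else if (a == "a^w") "agouti"
                    else shades)
      }
    }
    values <- sort(unique(values))
    if (!K$missing) {
      deriv <- c(deriv, paste0("K: ", paste(K$genotype, collapse = "/"),
                               if (K$detail$kb_present) " -> solid eumelanin coat; A-locus overridden by K^B (epistasis)"
                               else " -> k^y/k^y, A-locus expressed"))
      if (K$conflict) deriv <- c(deriv, K$note)
    } else deriv <- c(deriv, "K-locus missing: both K^B and k^y/k^y branches considered")
    if (!K$missing && !K$detail$kb_present) {
      deriv <- c(deriv, if (!is.na(A$expressed))
        paste0("A: expressed allele ", A$expressed, " (dominance A^y > a^w > a^t > a)")
        else paste0("A: expression ambiguous among {", paste(A$candidates, collapse = ", "), "}"))
    } else if (A$missing) {
      deriv <- c(deriv, "A-locus not evaluable but overridden (epistasis), prediction unaffected")
    }
    if (isTRUE(B$detail$complete)) {
      deriv <- c(deriv, paste0("B: ", paste(B$genotype, collapse = "/"), " -> ",
                               if (B$detail$brown) "two recessive TYRP1 alleles, eumelanin brown"
                               else "eumelanin black"))
      if (B$detail$rec_known <= 1 && any(values %in% eumelanin_shades)) {
        caveats <- c(caveats, "untested_allele_bc")
        deriv <- c(deriv, "B reconstruction carries an untested-brown-allele (b^c) caveat")
      }
    } else deriv <- c(deriv, "B-locus incomplete: eumelanin shade enumerated")
    if (!D$missing)
      deriv <- c(deriv, paste0("D: ", paste(D$genotype, collapse = "/"),
                               if (D$detail$dd) " -> dilution (black->blue, brown->isabella)" else " -> no dilution"))
    if (isTRUE(E$detail$mask) && length(values) == 1 &&
        values %in% eumelanin_shades &&
        (isTRUE(K$detail$kb_present) || identical(A$expressed, "a")))
      caveats <- c(caveats, "mask_not_visible_on_solid")
  }
  certainty <- if (length(values) == 1) "determined" else "ambiguous"
  new_prediction("coat_colour", values = values, certainty = certainty,
                 caveats = caveats, derivation = deriv, qualifiers = qualifiers)
}

#' Predict coat pattern from reconstructed locus states
#'
#' Spotting level from the MITF SINE (S/S solid or minimal white, S/S^p
#' pseudo-irish, S^p/S^p piebald/extreme white); merle overlay from PMEL
#' (M/m merle, M/M mainly white), suppressed to a `hidden_merle` caveat on
#' an e/e coat; harlequin only on a merle background with an H allele; tan
#' points when the A-locus expresses a^t on a eumelanin coat; a K^B/k^y
#' genotype adds the `possible_brindle` caveat (brindle is not genotyped by
#' the panel).
#'
#' @param states Named list of `dog_locus_state`.
#' @return A `dog_prediction` for `coat_pattern` whose values are composite
#'   tokens (see [trait_vocabulary()]).
#' @export
predict_coat_pattern <- function(states) {
  E <- states$E; K <- states$K; A <- states$A
  S <- states$S; M <- states$M; H <- states$H
  deriv <- character(0)
  caveats <- character(0)
  if (S$missing)
    return(new_prediction("coat_pattern", certainty = "not_evaluable",
                          derivation = c("S-locus not evaluable: MITF_INS missing", S$note)))
  spotting <- c("minimal_white", "pseudo_irish", "piebald")[S$detail$n_sp + 1]
  deriv <- c(deriv, paste0("S: ", paste(S$genotype, collapse = "/"), " -> ", spotting))
  if (S$conflict) { deriv <- c(deriv, S$note) }

  ee_opts <- if (E$missing) c(FALSE, TRUE) else E$detail$ee
  m_opts <- if (M$missing) 0:2 else M$detail$n_M
  h_opts <- if (H$missing) c(FALSE, TRUE) else H$detail$n_H >= 1
  kb_opts <- if (K$missing) c(TRUE, FALSE) else K$detail$kb_present
  a_opts <- if (A$missing && length(A$candidates) == 0) c("A^y", "a^w", "a^t", "a")
            else if (!is.na(A$expressed)) A$expressed else A$candidates

  values <- character(0)
  for (ee in ee_opts) for (m in m_opts) for (h in h_opts) for (kb in kb_opts) {
    tans <- if (ee || kb) FALSE else a_opts == "a^t"
    for (tan in unique(tans)) {
      merle <- if (m == 0 || ee) "none" else if (m == 1) "merle" else "mainly_white"
      harl <- merle == "merle" && h
      values <- c(values, compose_pattern(tan, spotting, merle, harl))
    }
  }
  values <- sort(unique(values))

  if (!M$missing) {
    if (M$detail$n_M >= 1 && isTRUE(E$detail$ee)) {
      caveats <- c(caveats, "hidden_merle")
      deriv <- c(deriv, "M allele present but e/e: merle pattern invisible (hidden merle)")
    } else if (M$detail$n_M == 1) deriv <- c(deriv, "M: M/m -> merle")
    else if (M$detail$n_M == 2) deriv <- c(deriv, "M: M/M -> mainly white (double merle)")
  }
  if (!H$missing && H$detail$n_H >= 1)
    deriv <- c(deriv, "H present: harlequin expressed only on a merle background")
  if (isTRUE(K$detail$het)) {
    caveats <- c(caveats, "possible_brindle")
    deriv <- c(deriv, "K^B/k^y: coat could be brindled (K^br not genotyped by this panel)")
  }
  if (identical(A$expressed, "a^t") && !isTRUE(E$detail$ee) && !isTRUE(K$detail$kb_present))
    deriv <- c(deriv, "A: a^t expressed -> tan points / tricolour pattern")

  certainty <- if (length(values) == 1) "determined" else "ambiguous"
  new_prediction("coat_pattern", values = values, certainty = certainty,
                 caveats = caveats, derivation = deriv)
}

#' Predict coat structure
#'
#' Three genes jointly: FGF5 hair length (short dominant), RSPO2
#' furnishings/wire (insertion dominant), KRT71 curl (semi-dominant: G/G
#' curly, A/G wavy, A/A smooth). The three axes combine into one composite
#' value; a missing marker drops only its own axis (certainty
#' `inconclusive`, the unknown axis marked `?`).
#'
#' @param profile A `dog_profile`.
#' @param panel A `dog_panel`.
#' @return A `dog_prediction` for `coat_structure`.
#' @export
predict_coat_structure <- function(profile, panel) {
  n_G <- allele_count(profile, "FGF5", "G")
  n_curl <- allele_count(profile, "KRT71", "G")
  n_ins <- allele_count(profile, "RSPO2", "Ins")
  if (all(is.na(c(n_G, n_curl, n_ins))))
    return(new_prediction("coat_structure", certainty = "not_evaluable",
                          derivation = "all three structure markers missing"))
  len <- if (is.na(n_G)) "?" else if (n_G >= 1) "short" else "long"
  curl <- if (is.na(n_curl)) "?" else c("smooth", "wavy", "curly")[n_curl + 1]
  furn <- if (is.na(n_ins)) "?" else if (n_ins >= 1) "furnishings" else "no_furnishings"
  deriv <- c(
    if (!is.na(n_G)) paste0("FGF5: ", if (n_G >= 1) "G present -> short hair (dominant)" else "T/T -> long hair")
    else "FGF5 missing: hair length axis not evaluable",
    if (!is.na(n_curl)) paste0("KRT71: ", c("A/A -> smooth", "A/G -> wavy (semi-dominant)", "G/G -> curly")[n_curl + 1])
    else "KRT71 missing: curl axis not evaluable",
    if (!is.na(n_ins)) paste0("RSPO2: ", if (n_ins >= 1) "insertion present -> furnishings (dominant)" else "no insertion -> no furnishings")
    else "RSPO2 missing: furnishings axis not evaluable")
  value <- compose_structure(len, curl, furn)
  certainty <- if (anyNA(c(n_G, n_curl, n_ins))) "inconclusive" else "determined"
  new_prediction("coat_structure",
                 values = if (certainty == "determined") value else value,
                 certainty = certainty, derivation = deriv)
}

#' Predict tail length
#'
#' The T-Box C>G mutation is dominant for a congenitally short tail
#' (bobtail) in heterozygotes; homozygous G/G is embryonically or
#' perinatally lethal, so an observed G/G call is reported `inconclusive`
#' with the `lethal_genotype_observed` caveat. A long-tail prediction
#' always carries two caveats: the tail may be docked
#' (`possible_docking`) and some breeds are bobtailed without this
#' mutation (`possible_ancestral_bobtail`).
#'
#' @inheritParams predict_coat_structure
#' @return A `dog_prediction` for `tail_length`.
#' @export
predict_tail <- function(profile, panel) {
  n_G <- allele_count(profile, "T-Box_C295G", "G")
  if (is.na(n_G))
    return(new_prediction("tail_length", certainty = "not_evaluable",
                          derivation = "T-Box_C295G missing"))
  if (n_G == 2)
    return(new_prediction("tail_length", certainty = "inconclusive",
                          caveats = "lethal_genotype_observed",
                          derivation = c("T-Box G/G observed: homozygosity for the bobtail mutation is embryonically/perinatally lethal",
                                         "call is biologically implausible; no tail prediction")))
  if (n_G == 1)
    return(new_prediction("tail_length", values = "bobtail",
                          certainty = "determined",
                          derivation = "T-Box G/C -> bobtail (dominant short-tail mutation)"))
  new_prediction("tail_length", values = "long_tail", certainty = "determined",
                 caveats = c("possible_docking", "possible_ancestral_bobtail"),
                 derivation = c("T-Box C/C -> long tail",
                                "caveat: tail may be artificially docked",
                                "caveat: some breeds are bobtailed without the T-Box mutation"))
}

#' Predict ear shape
#'
#' A single marker of unclarified dominance: G/G non-drop, A/A drop ears; a
#' heterozygote supports both states and is reported `ambiguous` with both
#' values. Every ear prediction carries the `possible_cropping` caveat.
#'
#' @inheritParams predict_coat_structure
#' @return A `dog_prediction` for `ear_shape`.
#' @export
predict_ear <- function(profile, panel) {
  n_A <- allele_count(profile, "BICFPJ1062878", "A")
  if (is.na(n_A))
    return(new_prediction("ear_shape", certainty = "not_evaluable",
                          derivation = "BICFPJ1062878 missing"))
  if (n_A == 1)
    return(new_prediction("ear_shape", values = c("drop", "non_drop"),
                          certainty = "ambiguous", caveats = "possible_cropping",
                          derivation = c("BICFPJ1062878 G/A: dominance not clarified, both ear shapes possible",
                                         "caveat: ears may be artificially cropped")))
  new_prediction("ear_shape",
                 values = if (n_A == 2) "drop" else "non_drop",
                 certainty = "determined", caveats = "possible_cropping",
                 derivation = c(paste0("BICFPJ1062878 ", if (n_A == 2) "A/A -> drop ears" else "G/G -> non-drop ears"),
                                "caveat: ears may be artificially cropped"))
}

#' Predict body size
#'
#' Binary classification from the IGF1R SNP: any A allele predicts "rather
#' small" (the dominance annotation sits on the A allele), G/G predicts
#' "rather tall".
#'
#' @inheritParams predict_coat_structure
#' @return A `dog_prediction` for `body_size`.
#' @export
predict_size <- function(profile, panel) {
  n_A <- allele_count(profile, "IGF1R", "A")
  if (is.na(n_A))
    return(new_prediction("body_size", certainty = "not_evaluable",
                          derivation = "IGF1R missing"))
  if (n_A >= 1)
    new_prediction("body_size", values = "rather_small", certainty = "determined",
                   derivation = paste0("IGF1R ", if (n_A == 2) "A/A" else "A/G",
                                       " -> rather small (A treated as dominant)"))
  else
    new_prediction("body_size", values = "rather_tall", certainty = "determined",
                   derivation = "IGF1R G/G -> rather tall")
}

#' Predict all six traits and assemble the identikit description
#'
#' Runs the six trait predictors on one genotype profile and assembles the
#' standardized composite description ("identikit") from the controlled
#' vocabulary. The function is pure: the same profile always produces a
#' byte-identical result.
#'
#' @param profile A `dog_profile`.
#' @param panel A `dog_panel`.
#' @return A `dog_identikit`: list with `sample_id`, `calls`, `predictions`
#'   (named list of six `dog_prediction`), `phrases` (named character,
#'   per-trait text) and `identikit` (single descriptive string).
#' @export
predict_all <- function(profile, panel) {
  states <- reconstruct_all(profile, panel)
  preds <- list(
    coat_colour = predict_coat_colour(states),
    coat_pattern = predict_coat_pattern(states),
    coat_structure = predict_coat_structure(profile, panel),
    tail_length = predict_tail(profile, panel),
    ear_shape = predict_ear(profile, panel),
    body_size = predict_size(profile, panel)
  )
  phrases <- identikit_phrases(preds)
  all_ne <- all(vapply(preds, function(p) p$certainty == "not_evaluable", TRUE))
  identikit <- if (all_ne) "no evaluable markers; no description possible"
               else paste(phrases, collapse = "; ")
  structure(list(sample_id = profile$sample_id, calls = profile$calls,
                 predictions = preds, phrases = phrases, identikit = identikit),
            class = "dog_identikit")
}

colour_words <- c(red_yellow_cream = "red/yellow/cream",
                  pale_cream = "pale cream (diluted)",
                  fawn_sable = "fawn/sable", agouti = "wild-type agouti",
                  black = "black", brown = "brown",
                  blue = "blue (diluted black)", isabella = "isabella (diluted brown)")
pattern_words <- c(tan_points = "tan points",
                   minimal_white = "minimal white spotting",
                   pseudo_irish = "pseudo-irish white spotting",
                   piebald = "piebald/extreme white spotting",
                   merle = "merle", mainly_white = "mainly white",
                   harlequin = "harlequin")
structure_words <- c(short = "short", long = "long", smooth = "smooth",
                     wavy = "wavy", curly = "curly",
                     furnishings = "furnishings",
                     no_furnishings = "no furnishings", `?` = "unknown")

identikit_phrases <- function(preds) {
  word <- function(map, v) unname(ifelse(v %in% names(map), map[v], v))
  # coat colour, folding in mask and (when determined) tan points
  pc <- preds$coat_colour
  colour <- switch(pc$certainty,
    determined = word(colour_words, pc$values),
    ambiguous = paste(word(colour_words, pc$values), collapse = " or "),
    "coat colour not evaluable")
  pat <- preds$coat_pattern
  pat_components <- if (pat$certainty %in% c("determined", "ambiguous"))
    strsplit(pat$values, "+", fixed = TRUE) else list()
  fold_tan <- pat$certainty == "determined" && "tan_points" %in% pat_components[[1]]
  if (fold_tan) colour <- paste0(colour, " with tan points")
  if ("melanistic_mask" %in% pc$qualifiers) colour <- paste0(colour, ", melanistic mask")
  pattern <- switch(pat$certainty,
    determined = {
      rest <- setdiff(pat_components[[1]], if (fold_tan) "tan_points" else character(0))
      paste(word(pattern_words, rest), collapse = ", ")
    },
    ambiguous = paste(vapply(pat_components, function(cp)
      paste(word(pattern_words, cp), collapse = ", "), ""), collapse = " or "),
    "coat pattern not evaluable")
  st <- preds$coat_structure
  structure_ <- if (st$certainty %in% c("determined", "inconclusive")) {
    cp <- strsplit(st$values, "+", fixed = TRUE)[[1]]
    paste0(word(structure_words, cp[1]), ", ", word(structure_words, cp[2]),
           " hair, ", word(structure_words, cp[3]))
  } else "coat structure not evaluable"
  tl <- preds$tail_length
  tail_ <- switch(tl$certainty,
    determined = c(long_tail = "long tail", bobtail = "bobtail")[tl$values],
    inconclusive = "tail length inconclusive",
    "tail length not evaluable")
  er <- preds$ear_shape
  ear <- switch(er$certainty,
    determined = c(drop = "drop ears", non_drop = "non-drop ears")[er$values],
    ambiguous = "drop or non-drop ears (ambiguous)",
    "ear shape not evaluable")
  sz <- preds$body_size
  size <- switch(sz$certainty,
    determined = c(rather_small = "rather small", rather_tall = "rather tall")[sz$values],
    "body size not evaluable")
  c(coat_colour = unname(colour), coat_pattern = unname(pattern),
    coat_structure = unname(structure_), tail_length = unname(tail_),
    ear_shape = unname(ear), body_size = unname(size))
}

#' @export
print.dog_identikit <- function(x, ...) {
  cat("dog_identikit ", x$sample_id, "\n  ", x$identikit, "\n", sep = "")
  for (t in names(x$predictions)) {
    p <- x$predictions[[t]]
    cat("  ", t, ": ", paste(p$values, collapse = " | "), " [", p$certainty, "]",
        if (length(p$caveats)) paste0(" caveats: ", paste(p$caveats, collapse = ",")) else "",
        "\n", sep = "")
  }
  invisible(x)
}
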