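test_that("locus reconstruction applies the documented shortcuts and flags", {
  panel <- test_panel()
  # e/e at MC1R overrides K and A
  p <- colour_profile(panel, "X1", c("e", "e"), c("k^y", "k^y"),
                      c("A^y", "a"), c("B", "B"), c("D", "D"))
  st <- dogphen:::reconstruct_all(p, panel)
  expect_equal(st$E$genotype, c("e", "e"))
  expect_equal(st$K$relevance, "overridden")
  expect_equal(st$A$relevance, "overridden")

  # E^m assigned to the non-e dosage: one e plus one M264V G is E^m/e
  p2 <- dogphen:::profile_from_states(panel, "X2",
    list("MC1R_306ter" = c("C", "T"), "MC1R_M264V" = c("G", "A")),
    base = dogphen:::base_states())
  stE <- reconstruct_locus(p2, "E", panel)
  expect_setequal(stE$genotype, c("E^m", "e"))
  expect_true(stE$detail$mask)

  # K^B/K^B with ASIP SINE missing: A not fully evaluable but overridden
  p3 <- dogphen:::profile_from_states(panel, "X3",
    c(list("ASIP_SINE" = NA),
      list("CBD103_S54" = c("DelGGG", "DelGGG"), "CBD103_S53" = c("C", "C"))),
    base = dogphen:::base_states())
  st3 <- dogphen:::reconstruct_all(p3, panel)
  expect_true(st3$A$missing)
  expect_equal(st3$A$relevance, "overridden")
  pred <- predict_coat_colour(st3)
  expect_equal(pred$certainty, "determined")
  expect_true(any(grepl("overridden", pred$derivation)))

  # disagreeing K markers set the conflict flag
  p4 <- dogphen:::profile_from_states(panel, "X4",
    list("CBD103_S54" = c("DelGGG", "GGG"), "CBD103_S53" = c("G", "G")),
    base = dogphen:::base_states())
  expect_true(reconstruct_locus(p4, "K", panel)$conflict)

  # MITF_SNP disagreement flags conflict but the SINE call wins
  p5 <- dogphen:::profile_from_states(panel, "X5",
    list("MITF_INS" = c("SINE", "no SINE"), "MITF_SNP" = c("A", "A")),
    base = dogphen:::base_states())
  st5 <- reconstruct_locus(p5, "S", panel)
  expect_true(st5$conflict)
  expect_equal(st5$detail$n_sp, 1L)
})

test_that("coat colour cascade reproduces the narrated worked examples", {
  panel <- test_panel()
  # e/e dog: phaeomelanin coat whatever B carries
  p <- colour_profile(panel, "W1", c("e", "e"), c("k^y", "k^y"),
                      c("a^w", "a^w"), c("B", "b^s"), c("D", "D"))
  pr <- predict_coat_colour(dogphen:::reconstruct_all(p, panel))
  expect_equal(pr$values, "red_yellow_cream")
  expect_equal(pr$certainty, "determined")

  # compound heterozygote b^s/b^d is brown
  p2 <- colour_profile(panel, "W2", c("E", "E"), c("K^B", "K^B"),
                       c("a^w", "a^w"), c("b^s", "b^d"), c("D", "D"))
  expect_equal(predict_coat_colour(dogphen:::reconstruct_all(p2, panel))$values,
               "brown")

  # diluted black is blue, with brindle possible on K^B/k^y and the
  # untested-brown-allele caveat on a B/B reconstruction
  p3 <- colour_profile(panel, "W3", c("E", "E"), c("K^B", "k^y"),
                       c("a^w", "a^w"), c("B", "B"), c("d", "d"))
  st3 <- dogphen:::reconstruct_all(p3, panel)
  pr3 <- predict_coat_colour(st3)
  expect_equal(pr3$values, "blue")
  expect_true("untested_allele_bc" %in% pr3$caveats)
  expect_true("possible_brindle" %in% predict_coat_pattern(st3)$caveats)
})

test_that("coat colour cascade equals the brute-force decision-table oracle", {
  panel <- test_panel()
  Es <- allele_pairs(c("E^m", "E", "e"))
  Ks <- allele_pairs(c("K^B", "k^y"))
  As <- allele_pairs(c("A^y", "a^w", "a^t", "a"))
  Bs <- allele_pairs(c("B", "b^s", "b^d"))
  Ds <- allele_pairs(c("D", "d"))
  n_checked <- 0L
  for (E in Es) for (K in Ks) for (A in As) for (B in Bs) for (D in Ds) {
    p <- colour_profile(panel, "T", E, K, A, B, D)
    pred <- predict_coat_colour(dogphen:::reconstruct_all(p, panel))
    expected <- oracle_colour(E, K, A, B, D)
    if (!identical(pred$values, expected) || pred$certainty != "determined") {
      fail(sprintf("E=%s K=%s A=%s B=%s D=%s: cascade %s (%s), oracle %s",
                   paste(E, collapse = "/"), paste(K, collapse = "/"),
                   paste(A, collapse = "/"), paste(B, collapse = "/"),
                   paste(D, collapse = "/"),
                   paste(pred$values, collapse = "|"), pred$certainty, expected))
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 6 * 3 * 10 * 6 * 3)
})

test_that("e/e epistasis makes the fur colour invariant to K and A substitutions", {
  panel <- test_panel()
  Ks <- allele_pairs(c("K^B", "k^y"))
  As <- allele_pairs(c("A^y", "a^w", "a^t", "a"))
  for (B in list(c("B", "B"), c("b^s", "b^d"))) for (D in list(c("D", "D"), c("d", "d"))) {
    vals <- character(0)
    for (K in Ks) for (A in As) {
      p <- colour_profile(panel, "EE", c("e", "e"), K, A, B, D)
      pr <- predict_coat_colour(dogphen:::reconstruct_all(p, panel))
      expect_equal(pr$certainty, "determined")
      vals <- c(vals, pr$values)
    }
    expect_length(unique(vals), 1)
  }
})

test_that("promoting a recessive allele to its dominant counterpart never flips a dominant phenotype to the recessive one", {
  panel <- test_panel()
  set.seed(7)
  promote <- list(
    D = list(from = "d", to = "D",
             recessive_vals = c("blue", "isabella", "pale_cream")),
    B = list(from = "b^s", to = "B", recessive_vals = c("brown", "isabella")),
    K = list(from = "k^y", to = "K^B", recessive_vals = c("fawn_sable", "agouti"))
  )
  for (rep in 1:150) {
    E <- sample(c("E^m", "E", "e"), 2, replace = TRUE)
    K <- sample(c("K^B", "k^y"), 2, replace = TRUE)
    A <- sample(c("A^y", "a^w", "a^t", "a"), 2, replace = TRUE)
    B <- sample(c("B", "b^s", "b^d"), 2, replace = TRUE)
    D <- sample(c("D", "d"), 2, replace = TRUE)
    base_val <- predict_coat_colour(dogphen:::reconstruct_all(
      colour_profile(panel, "M0", E, K, A, B, D), panel))$values
    geno <- list(E = E, K = K, A = A, B = B, D = D)
    for (loc in names(promote)) {
      pm <- promote[[loc]]
      idx <- which(geno[[loc]] == pm$from)
      if (!length(idx)) next
      g2 <- geno
      g2[[loc]][idx[1]] <- pm$to
      new_val <- predict_coat_colour(dogphen:::reconstruct_all(
        colour_profile(panel, "M1", g2$E, g2$K, g2$A, g2$B, g2$D), panel))$values
      # if the dominant phenotype was already shown, adding another dominant
      # allele must not produce the locus's recessive phenotype
      if (!base_val %in% pm$recessive_vals)
        expect_false(new_val %in% pm$recessive_vals,
                     label = paste(loc, base_val, "->", new_val))
    }
  }
  # single-marker dominance: adding the dominant allele never yields the
  # recessive phenotype
  p_short <- dogphen:::profile_from_states(panel, "S1",
    list("FGF5" = c("G", "T")), base = dogphen:::base_states())
  expect_equal(predict_coat_structure(p_short, panel)$values,
               "short+smooth+no_furnishings")
  p_bob <- dogphen:::profile_from_states(panel, "S2",
    list("T-Box_C295G" = c("G", "C")), base = dogphen:::base_states())
  expect_equal(predict_tail(p_bob, panel)$values, "bobtail")
  p_small <- dogphen:::profile_from_states(panel, "S3",
    list("IGF1R" = c("G", "A")), base = dogphen:::base_states())
  expect_equal(predict_size(p_small, panel)$values, "rather_small")
})

test_that("coat pattern rules: spotting series, merle, hidden merle, harlequin, tan points", {
  panel <- test_panel()
  base <- dogphen:::base_states()
  mk <- function(id, states) dogphen:::profile_from_states(panel, id, states, base = base)
  pat <- function(p) predict_coat_pattern(dogphen:::reconstruct_all(p, panel))

  expect_equal(pat(mk("S0", list()))$values, "minimal_white")
  expect_equal(pat(mk("S1", list("MITF_INS" = c("no SINE", "SINE"),
                                 "MITF_SNP" = c("A", "G"))))$values, "pseudo_irish")
  expect_equal(pat(mk("S2", list("MITF_INS" = c("SINE", "SINE"),
                                 "MITF_SNP" = c("G", "G"))))$values, "piebald")
  # merle and harlequin on a merle background
  expect_equal(pat(mk("M1", list("PMEL" = c("SINE", "no SINE"))))$values,
               "minimal_white+merle")
  expect_equal(pat(mk("M2", list("PMEL" = c("SINE", "no SINE"),
                                 "PSMB7" = c("G", "T"))))$values,
               "minimal_white+merle+harlequin")
  # harlequin without merle is not expressed
  expect_equal(pat(mk("M3", list("PSMB7" = c("G", "T"))))$values, "minimal_white")
  # double merle is mainly white
  expect_equal(pat(mk("M4", list("PMEL" = c("SINE", "SINE"))))$values,
               "minimal_white+mainly_white")
  # hidden merle: e/e suppresses the pattern and sets the caveat
  hm <- pat(mk("M5", list("PMEL" = c("SINE", "no SINE"),
                          "MC1R_306ter" = c("T", "T"))))
  expect_equal(hm$values, "minimal_white")
  expect_true("hidden_merle" %in% hm$caveats)
  # a^t on a eumelanin background gives tan points; K^B masks them
  expect_equal(pat(mk("T1", list("ASIP_SINE" = c("SINE", "SINE"))))$values,
               "tan_points+minimal_white")
  expect_equal(pat(mk("T2", list("ASIP_SINE" = c("SINE", "SINE"),
                                 "CBD103_S54" = c("DelGGG", "DelGGG"),
                                 "CBD103_S53" = c("C", "C"))))$values,
               "minimal_white")
  # both MITF markers failed: pattern not evaluable
  expect_equal(pat(mk("T3", list("MITF_INS" = NA, "MITF_SNP" = NA)))$certainty,
               "not_evaluable")
})

test_that("structure, tail, ear and size follow their single-locus rules", {
  panel <- test_panel()
  base <- dogphen:::base_states()
  mk <- function(id, states) dogphen:::profile_from_states(panel, id, states, base = base)

  st <- predict_coat_structure(mk("C1", list("FGF5" = c("T", "T"),
                                             "KRT71" = c("A", "G"))), panel)
  expect_equal(st$values, "long+wavy+no_furnishings")
  expect_equal(st$certainty, "determined")
  miss <- predict_coat_structure(mk("C2", list("RSPO2" = NA)), panel)
  expect_equal(miss$certainty, "inconclusive")
  expect_match(miss$values, "short\\+smooth\\+\\?")
  expect_equal(predict_coat_structure(mk("C3", list("RSPO2" = c("Ins", "no Ins"))),
                                      panel)$values, "short+smooth+furnishings")

  tl <- predict_tail(mk("T1", list()), panel)
  expect_equal(tl$values, "long_tail")
  expect_true(all(c("possible_docking", "possible_ancestral_bobtail") %in% tl$caveats))
  expect_equal(predict_tail(mk("T2", list("T-Box_C295G" = c("G", "C"))), panel)$values,
               "bobtail")
  lethal <- predict_tail(mk("T3", list("T-Box_C295G" = c("G", "G"))), panel)
  expect_equal(lethal$certainty, "inconclusive")
  expect_true("lethal_genotype_observed" %in% lethal$caveats)

  expect_equal(predict_ear(mk("E1", list("BICFPJ1062878" = c("A", "A"))), panel)$values,
               "drop")
  amb <- predict_ear(mk("E2", list("BICFPJ1062878" = c("G", "A"))), panel)
  expect_equal(amb$certainty, "ambiguous")
  expect_setequal(amb$values, c("drop", "non_drop"))
  expect_true("possible_cropping" %in% amb$caveats)
  expect_equal(predict_ear(mk("E3", list("BICFPJ1062878" = NA)), panel)$certainty,
               "not_evaluable")

  expect_equal(predict_size(mk("Z1", list("IGF1R" = c("A", "A"))), panel)$values,
               "rather_small")
  expect_equal(predict_size(mk("Z2", list()), panel)$values, "rather_tall")
})

test_that("predict_all is deterministic and equal genotypes give identical identikits", {
  panel <- test_panel()
  coh <- validation_cohorts(panel)$blind
  sids <- vapply(coh$profiles, `[[`, "", "sample_id")
  r1 <- predict_all(coh$profiles[[which(sids == "D4926")]], panel)
  r1b <- predict_all(coh$profiles[[which(sids == "D4926")]], panel)
  expect_identical(r1, r1b)
  r2 <- predict_all(coh$profiles[[which(sids == "D4928")]], panel)
  expect_identical(r1$identikit, r2$identikit)
  expect_match(r1$identikit, "black with tan points")
  expect_match(r1$identikit, "long, smooth hair")
  expect_match(r1$identikit, "long tail")
  expect_match(r1$identikit, "rather tall")
})
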