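test_that("simulator configuration validates probabilities and frequencies", {
  expect_error(sim_config(10), "seed")
  expect_error(sim_config(10, exception_rates = list(p_bc = 1.5), seed = 1),
               "probability")
  expect_error(sim_config(10, allele_freqs = list(D = c(D = 0.7, d = 0.2)),
                          seed = 1), "sum")
  cfg <- sim_config(10, seed = 1)
  expect_s3_class(cfg, "dog_simconfig")
  expect_equal(cfg$exception_rates$p_bc, 0.05)
})

test_that("same seed gives identical cohorts, different seeds differ", {
  panel <- test_panel()
  cfg <- sim_config(n_samples = 30, seed = 2024)
  c1 <- simulate_cohort(cfg, panel)
  c2 <- simulate_cohort(cfg, panel)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sim_config(n_samples = 30, seed = 2025), panel)
  expect_false(identical(c1$profiles, c3$profiles))
})

test_that("zero-noise cohorts close the loop: determined predictions match phenotypes", {
  panel <- test_panel()
  zero <- list(p_bc = 0, p_ancestral_bobtail = 0, p_docked = 0,
               p_ear_drop_given_het = 0, p_size_misclass = 0)
  cfg <- sim_config(n_samples = 200, exception_rates = zero, seed = 11)
  coh <- simulate_cohort(cfg, panel)
  n_checked <- 0L
  for (p in coh$profiles) {
    res <- predict_all(p, panel)
    ph <- coh$phenotypes[coh$phenotypes$sample_id == p$sample_id, ]
    for (tr in names(res$predictions)) {
      pred <- res$predictions[[tr]]
      if (pred$certainty != "determined") next
      obs <- ph$value[ph$trait == tr]
      expect_identical(obs, pred$values,
                       label = paste(p$sample_id, tr))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 1000)  # most of 200 dogs x 6 traits are determined
})

test_that("lethal T-Box homozygotes never occur in simulated cohorts", {
  panel <- test_panel()
  coh <- simulate_cohort(sim_config(2000, seed = 5), panel)
  gg <- vapply(coh$profiles, function(p)
    identical(p$calls$`T-Box_C295G`$alleles, c("G", "G")), TRUE)
  expect_false(any(gg))
})

test_that("per-marker genotype frequencies follow Hardy-Weinberg within 3 SE", {
  panel <- test_panel()
  n <- 5000
  coh <- simulate_cohort(sim_config(n, seed = 31), panel)
  freqs <- default_allele_freqs()
  for (mk in c("IGF1R", "BICFPJ1062878")) {
    q <- freqs[[mk]][["A"]]
    counts <- table(factor(vapply(coh$profiles, function(p)
      sum(p$calls[[mk]]$alleles == "A"), 0L), levels = 0:2))
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    for (k in 1:3) {
      se <- sqrt(n * expected[k] * (1 - expected[k]))
      expect_lt(abs(counts[k] - n * expected[k]), 3 * se,
                label = paste(mk, "genotype class", k - 1))
    }
  }
})

test_that("exception-channel frequencies recover their configured rates within 3 SE", {
  panel <- test_panel()
  n <- 5000
  rates <- list(p_bc = 0.10, p_ancestral_bobtail = 0.15, p_docked = 0.10,
                p_ear_drop_given_het = 0.40, p_size_misclass = 0.25)
  coh <- simulate_cohort(sim_config(n, exception_rates = rates, seed = 77), panel)
  hf <- coh$hidden_factors
  check_rate <- function(hits, trials, p, label) {
    se <- sqrt(trials * p * (1 - p))
    expect_lt(abs(hits - trials * p), 3 * se, label = label)
  }
  # hidden b^c per wild-type-genotyped TYRP1 haplotype
  n_B_hap <- sum(vapply(coh$profiles, function(p)
    sum(p$calls$TYRP1_Q331ter$alleles == "B") +
      sum(p$calls$TYRP1_345delP$alleles == "B") - 2L, 0L))
  check_rate(sum(hf$n_hidden_bc), n_B_hap, rates$p_bc, "p_bc")
  cc <- vapply(coh$profiles, function(p)
    identical(p$calls$`T-Box_C295G`$alleles, c("C", "C")), TRUE)
  check_rate(sum(hf$ancestral_bobtail), sum(cc), rates$p_ancestral_bobtail,
             "p_ancestral_bobtail")
  check_rate(sum(hf$docked), sum(cc & !hf$ancestral_bobtail), rates$p_docked,
             "p_docked")
  check_rate(sum(hf$ear_het_drop, na.rm = TRUE), sum(hf$ear_het),
             rates$p_ear_drop_given_het, "p_ear_drop_given_het")
  check_rate(sum(hf$size_flipped), n, rates$p_size_misclass, "p_size_misclass")
})

test_that("validation cohorts reproduce the narrated structures", {
  panel <- test_panel()
  coh <- validation_cohorts(panel)
  expect_named(coh, c("pilot", "coat_colour", "coat_structure", "tail_length",
                      "ear_shape", "body_size", "blind"))
  expect_length(coh$pilot$profiles, 12)
  expect_length(coh$coat_colour$profiles, 16)
  for (nm in c("coat_structure", "tail_length", "ear_shape", "body_size"))
    expect_length(coh[[nm]]$profiles, 10)
  expect_length(coh$blind$profiles, 9)

  # three coat-colour dogs with failed ASIP SINE sequencing
  asip_missing <- vapply(coh$coat_colour$profiles, function(p)
    is.null(p$calls$ASIP_SINE$alleles), TRUE)
  expect_equal(sum(asip_missing), 3)

  # six heterozygous b^s dogs in the coat-colour set
  bs_het <- vapply(coh$coat_colour$profiles, function(p)
    !is.null(p$calls$TYRP1_Q331ter$alleles) &&
      sum(p$calls$TYRP1_Q331ter$alleles == "b^s") == 1, TRUE)
  expect_equal(sum(bs_het), 6)

  # ear set: six heterozygotes, one failed marker
  ear_het <- vapply(coh$ear_shape$profiles, function(p) {
    al <- p$calls$BICFPJ1062878$alleles
    !is.null(al) && length(unique(al)) == 2
  }, TRUE)
  expect_equal(sum(ear_het), 6)
  expect_equal(sum(vapply(coh$ear_shape$profiles, function(p)
    is.null(p$calls$BICFPJ1062878$alleles), TRUE)), 1)

  # every fixture sample carries a provenance note
  for (nm in names(coh))
    expect_true(all(nzchar(coh[[nm]]$notes$note)))
})

test_that("the blind cohort contains exactly one triple identical outside the ear marker", {
  panel <- test_panel()
  blind <- validation_cohorts(panel)$blind
  non_ear <- setdiff(names(panel$markers), "BICFPJ1062878")
  key <- vapply(blind$profiles, function(p)
    paste(vapply(non_ear, function(id) {
      al <- p$calls[[id]]$alleles
      if (is.null(al)) "NA" else paste(al, collapse = "/")
    }, ""), collapse = ";"), "")
  grp <- table(key)
  expect_equal(sort(unname(as.vector(grp)), decreasing = TRUE)[1], 3)
  expect_equal(sum(grp == 3), 1)
  trio <- which(key == names(grp)[grp == 3])
  sids <- vapply(blind$profiles, `[[`, "", "sample_id")
  expect_setequal(sids[trio], c("D4926", "D4928", "D4931"))
  # the trio differs only at the ear marker
  ears <- lapply(blind$profiles[trio], function(p) p$calls$BICFPJ1062878$alleles)
  expect_gt(length(unique(vapply(ears, paste, "", collapse = "/"))), 1)
})
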