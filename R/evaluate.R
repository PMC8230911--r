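# Genotype-phenotype concordance accounting.

#' Score predictions against observed phenotypes
#'
#' Builds the full sample x trait matrix of concordance cells. Outcomes:
#' `match` / `mismatch` for determined predictions against an assessable
#' observation; `ambiguous_consistent` / `ambiguous` when the prediction
#' holds a finite value set (e.g. the heterozygous ear marker);
#' `inconclusive` when a rule fired but was uninformative;
#' `not_assessable_phenotype` when the observation is unavailable (cropped
#' tail, ears not visible on the photo); `not_evaluable_genotype` when the
#' genotype gave no prediction. Per-trait accuracy counts
#' matches / (matches + mismatches); ambiguous cells are reported
#' separately and never counted as matches.
#'
#' @param predictions List of `dog_identikit` from [predict_all()].
#' @param phenotypes Phenotype data frame (see [read_phenotype_table()]).
#' @return A `dog_concordance`: list with `cells` (long data frame) and
#'   `accuracy` (per-trait outcome counts and accuracy).
#' @export
score_cohort <- function(predictions, phenotypes) {
  pred_ids <- vapply(predictions, `[[`, "", "sample_id")
  names(predictions) <- pred_ids
  pheno_ids <- unique(phenotypes$sample_id)
  orphans <- c(setdiff(pheno_ids, pred_ids), setdiff(pred_ids, pheno_ids))
  if (length(orphans))
    stop_dogphen("sample_id mismatch between predictions and phenotypes: ",
                 paste(unique(orphans), collapse = ", "))
  traits <- trait_categories()
  rows <- list()
  for (sid in sort(pred_ids)) {
    preds <- predictions[[sid]]$predictions
    for (tr in traits) {
      p <- preds[[tr]]
      ph <- phenotypes[phenotypes$sample_id == sid & phenotypes$trait == tr, ]
      obs <- if (nrow(ph) >= 1 && ph$assessable[1]) ph$value[1] else NA_character_
      note <- if (nrow(ph) >= 1) ph$note[1] else ""
      outcome <-
        if (is.na(obs)) "not_assessable_phenotype"
        else if (p$certainty == "not_evaluable") "not_evaluable_genotype"
        else if (p$certainty == "inconclusive") "inconclusive"
        else if (p$certainty == "ambiguous") {
          if (obs %in% p$values) "ambiguous_consistent" else "ambiguous"
        } else if (identical(obs, p$values)) "match" else "mismatch"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, trait = tr, outcome = outcome,
        predicted = paste(p$values, collapse = "|"),
        observed = if (is.na(obs)) "" else obs,
        note = note, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  acc <- do.call(rbind, lapply(traits, function(tr) {
    oc <- cells$outcome[cells$trait == tr]
    m <- sum(oc == "match"); mm <- sum(oc == "mismatch")
    data.frame(trait = tr, match = m, mismatch = mm,
               ambiguous = sum(oc %in% c("ambiguous", "ambiguous_consistent")),
               inconclusive = sum(oc == "inconclusive"),
               not_assessable = sum(oc == "not_assessable_phenotype"),
               not_evaluable = sum(oc == "not_evaluable_genotype"),
               accuracy = if (m + mm > 0) m / (m + mm) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, accuracy = acc), class = "dog_concordance")
}

#' @export
print.dog_concordance <- function(x, ...) {
  cat("dog_concordance:", length(unique(x$cells$sample_id)), "samples x",
      length(unique(x$cells$trait)), "traits\n")
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}

#' Genotyping summary counts
#'
#' @param profiles List of `dog_profile`.
#' @param panel A `dog_panel`.
#' @return List with `samples`, `markers`, `attempted` (samples x markers),
#'   `missing` and `called` counts.
#' @export
summarize_genotyping <- function(profiles, panel) {
  n <- length(profiles)
  k <- length(panel$markers)
  missing <- sum(vapply(profiles, function(p)
    sum(vapply(p$calls, is_missing_call, TRUE)), 0L))
  list(samples = n, markers = k, attempted = n * k,
       missing = missing, called = n * k - missing)
}

#' Render the concordance heatmap
#'
#' Writes the sample x trait outcome grid as a deterministic TSV (the
#' testable artifact) and, optionally, as a colour-coded tile plot (the
#' cosmetic twin). Rows and columns are sorted so identical inputs give a
#' byte-identical TSV.
#'
#' @param scored A `dog_concordance` from [score_cohort()].
#' @param tsv_path Output TSV path.
#' @param image_path Optional PNG path; plotting failures (e.g. no usable
#'   graphics device) are downgraded to a warning.
#' @return `tsv_path`, invisibly.
#' @export
render_heatmap <- function(scored, tsv_path, image_path = NULL) {
  cells <- scored$cells
  sids <- sort(unique(cells$sample_id))
  traits <- trait_categories()
  wide <- matrix("", nrow = length(sids), ncol = length(traits),
                 dimnames = list(sids, traits))
  for (i in seq_len(nrow(cells)))
    wide[cells$sample_id[i], cells$trait[i]] <- cells$outcome[i]
  df <- data.frame(sample_id = rownames(wide), wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image_path)) {
    tryCatch({
      cells$outcome <- factor(cells$outcome, levels = c(
        "match", "ambiguous_consistent", "ambiguous", "mismatch",
        "inconclusive", "not_assessable_phenotype", "not_evaluable_genotype"))
      pal <- c(match = "#1a9850", ambiguous_consistent = "#91cf60",
               ambiguous = "#fee08b", mismatch = "#d73027",
               inconclusive = "#bdbdbd", not_assessable_phenotype = "#f0f0f0",
               not_evaluable_genotype = "#636363")
      gp <- ggplot2::ggplot(cells, ggplot2::aes(
        x = factor(trait, levels = traits),
        y = factor(sample_id, levels = rev(sids)), fill = outcome)) +
        ggplot2::geom_tile(colour = "white", linewidth = 0.5) +
        ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
        ggplot2::labs(x = NULL, y = NULL, fill = "outcome") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
      ggplot2::ggsave(image_path, gp, width = 7,
                      height = 1 + 0.3 * length(sids), dpi = 150)
    }, error = function(e) warning("heatmap image not written: ", conditionMessage(e)))
  }
  invisible(tsv_path)
}
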