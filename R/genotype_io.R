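# External representations: genotype TSV, VCF, phenotype TSV, JSON report.

#' Read a genotype table
#'
#' Tab-separated, one row per sample. Column `sample_id` plus one column
#' per marker holding slash-joined nucleotide/presence states exactly as in
#' the panel (e.g. `C/T`, `GGG/DelGGG`, `SINE/no SINE`); allele symbols are
#' accepted as a fallback. Empty cells become MISSING calls.
#'
#' @param path TSV file.
#' @param panel A `dog_panel`.
#' @return List of `dog_profile`, one per input row. Unknown marker columns
#'   are reported with a warning; a cell that matches no allele raises an
#'   error naming the sample and marker.
#' @export
read_genotype_table <- function(path, panel) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(tab))
    stop_dogphen("genotype table must have a 'sample_id' column")
  unknown <- setdiff(names(tab), c("sample_id", names(panel$markers)))
  if (length(unknown))
    warning("ignoring unknown marker column(s): ", paste(unknown, collapse = ", "))
  marker_cols <- intersect(names(tab), names(panel$markers))
  lapply(seq_len(nrow(tab)), function(i) {
    sid <- tab$sample_id[i]
    calls <- list()
    for (id in marker_cols) {
      cell <- tab[[id]][i]
      if (is.na(cell) || !nzchar(cell)) {
        calls[[id]] <- genotype_call(panel, id, NULL)
      } else {
        states <- strsplit(cell, "/", fixed = TRUE)[[1]]
        calls[[id]] <- tryCatch(
          call_from_states(panel, id, states),
          dogphen_allele_error = function(e) stop_dogphen(
            "sample ", sid, ", marker ", id, ": ", conditionMessage(e),
            class = "dogphen_allele_error")
        )
      }
    }
    genotype_profile(sid, calls, panel)
  })
}

#' Write profiles as a genotype table
#'
#' @param profiles List of `dog_profile`.
#' @param path Output TSV path.
#' @param panel A `dog_panel`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(profiles, path, panel) {
  ids <- names(panel$markers)
  rows <- vapply(profiles, function(p) {
    cells <- vapply(ids, function(id) {
      call <- p$calls[[id]]
      if (is_missing_call(call)) "" else paste(call$raw_states, collapse = "/")
    }, "")
    paste(c(p$sample_id, cells), collapse = "\t")
  }, "")
  writeLines(c(paste(c("sample_id", ids), collapse = "\t"), rows), path)
  invisible(path)
}

# REF/ALT sequences used when emitting panel markers as VCF records
marker_vcf_alleles <- function(marker) {
  al <- marker$alleles
  if (marker$marker_type == "SNP") {
    list(ref = al$name[1], alt = al$name[2], REF = al$state[1], ALT = al$state[2])
  } else if (marker$marker_type %in% c("SINE", "intermediate_INDEL")) {
    long <- marker$long_allele
    short <- setdiff(al$name, long)[1]
    list(ref = short, alt = long, REF = "N", ALT = "<INS:ME:SINE>")
  } else { # microINDEL: explicit anchored alleles, block taken from the state
    long <- marker$long_allele
    short <- setdiff(al$name, long)[1]
    block <- al$state[al$name == long]
    list(ref = short, alt = long, REF = "A", ALT = paste0("A", block))
  }
}

#' Write profiles as VCF
#'
#' Diploid GT-only VCF v4.2; SNPs as explicit REF/ALT bases, SINE and
#' intermediate insertions as the symbolic ALT `<INS:ME:SINE>`, microINDELs
#' as anchored explicit alleles. Records carry the marker id in the ID
#' column; CanFam3.1 coordinates are emitted when the panel has them.
#'
#' @param profiles List of `dog_profile`.
#' @param path Output `.vcf` path (plain text).
#' @param panel A `dog_panel`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(profiles, path, panel) {
  sids <- vapply(profiles, `[[`, "", "sample_id")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dogphen",
    "##ALT=<ID=INS:ME:SINE,Description=\"SINE mobile element insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sids), collapse = "\t")
  )
  body <- character(0)
  i <- 0
  for (id in names(panel$markers)) {
    i <- i + 1
    m <- panel$markers[[id]]
    va <- marker_vcf_alleles(m)
    chrom <- if (is.na(m$chrom)) "un" else m$chrom
    pos <- if (is.na(m$pos)) i * 1000L else m$pos
    gts <- vapply(profiles, function(p) {
      call <- p$calls[[id]]
      if (is_missing_call(call)) return("./.")
      codes <- ifelse(call$alleles == va$ref, 0L, 1L)
      paste(sort(codes), collapse = "/")
    }, "")
    body <- c(body, paste(c(chrom, pos, id, va$REF, va$ALT, ".", "PASS", ".",
                            "GT", gts), collapse = "\t"))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype profiles from a VCF
#'
#' Records are matched to panel markers by the ID column, or by
#' chromosome+position when the panel carries a coordinate. Each sample
#' column yields one profile; unmatched panel markers become MISSING.
#' A symbolic insertion ALT maps to the marker's insertion-bearing allele;
#' for explicit alleles the longer sequence is the insertion-bearing one and
#' SNP bases are matched to allele states. Non-diploid GT or an unmappable
#' ALT skips that marker for the sample with a warning.
#'
#' @param path VCF file (vcfR handles plain or gzipped).
#' @param panel A `dog_panel`.
#' @return List of `dog_profile`, one per VCF sample column.
#' @export
read_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  sids <- colnames(gt)

  # map VCF row -> marker id
  row_marker <- rep(NA_character_, nrow(fix))
  for (r in seq_len(nrow(fix))) {
    id <- fix[r, "ID"]
    if (!is.na(id) && id %in% names(panel$markers)) {
      row_marker[r] <- id
    } else {
      for (m in panel$markers) {
        if (!is.na(m$chrom) && !is.na(m$pos) &&
            isTRUE(unname(fix[r, "CHROM"]) == m$chrom) &&
            isTRUE(as.integer(fix[r, "POS"]) == as.integer(m$pos))) {
          row_marker[r] <- m$marker_id
          break
        }
      }
    }
  }

  lapply(sids, function(sid) {
    calls <- list()
    for (r in which(!is.na(row_marker))) {
      id <- row_marker[r]
      m <- panel$markers[[id]]
      ref <- fix[r, "REF"]; alt <- fix[r, "ALT"]
      # map REF/ALT (codes 0/1) to allele symbols
      if (grepl("^<INS", alt)) {
        long <- m$long_allele
        allele_of <- c(`0` = setdiff(m$alleles$name, long)[1], `1` = long)
      } else if (nchar(ref) != nchar(alt)) {
        long <- m$long_allele
        short <- setdiff(m$alleles$name, long)[1]
        allele_of <- if (nchar(alt) > nchar(ref)) c(`0` = short, `1` = long)
                     else c(`0` = long, `1` = short)
      } else {
        i0 <- match(ref, m$alleles$state); i1 <- match(alt, m$alleles$state)
        if (is.na(i0) || is.na(i1)) {
          warning("marker ", id, ": REF/ALT ", ref, "/", alt,
                  " match no allele state; sample ", sid, " skipped for this marker")
          next
        }
        allele_of <- c(`0` = m$alleles$name[i0], `1` = m$alleles$name[i1])
      }
      g <- gt[r, sid]
      if (is.na(g) || g %in% c("./.", ".|.", ".")) {
        calls[[id]] <- genotype_call(panel, id, NULL)
        next
      }
      codes <- strsplit(g, "[/|]")[[1]]
      if (length(codes) != 2 || !all(codes %in% c("0", "1"))) {
        warning("marker ", id, ", sample ", sid, ": GT '", g,
                "' is not diploid 0/1-coded; marker skipped")
        next
      }
      calls[[id]] <- genotype_call(panel, id, unname(allele_of[codes]))
    }
    genotype_profile(sid, calls, panel)
  })
}

#' Read an observed-phenotype table
#'
#' Long-format TSV with columns `sample_id`, `trait`, `value`,
#' `assessable` (TRUE/FALSE), `note`. An unobservable trait (e.g. a cropped
#' tail, ears not visible on the photo) has `assessable = FALSE` and no
#' value; values are validated against [trait_vocabulary()].
#'
#' @param path TSV file.
#' @return Data frame of phenotype records.
#' @export
read_phenotype_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "trait", "value", "assessable")
  if (!all(need %in% names(tab)))
    stop_dogphen("phenotype table needs columns: ", paste(need, collapse = ", "))
  tab$assessable <- toupper(tab$assessable) %in% c("TRUE", "T", "1", "YES")
  if (!"note" %in% names(tab)) tab$note <- ""
  tab$note[is.na(tab$note)] <- ""
  for (i in seq_len(nrow(tab))) {
    if (!tab$assessable[i]) {
      if (nzchar(tab$value[i]) && !is.na(tab$value[i]))
        stop_dogphen("sample ", tab$sample_id[i], ", trait ", tab$trait[i],
                     ": unobservable trait must carry no value")
      next
    }
    ok <- check_vocab_value(tab$trait[i], tab$value[i])
    if (!isTRUE(ok))
      stop_dogphen("sample ", tab$sample_id[i], ": ", ok,
                   class = "dogphen_vocab_error")
  }
  tab[, c("sample_id", "trait", "value", "assessable", "note")]
}

#' Write an observed-phenotype table
#' @param phenotypes Data frame as returned by [read_phenotype_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable prediction report
#'
#' One object per sample: genotype calls, the six trait predictions with
#' certainty, caveats and derivation chain, and the identikit text. Output
#' is byte-stable for identical inputs (samples and keys sorted). A flat
#' TSV summary (sample x trait value/certainty) is written alongside when
#' `summary_path` is given.
#'
#' @param results List of `dog_identikit` objects from [predict_all()].
#' @param path Output JSON path.
#' @param summary_path Optional TSV summary path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, summary_path = NULL) {
  sids <- vapply(results, `[[`, "", "sample_id")
  results <- results[order(sids)]
  samples <- lapply(results, function(r) {
    calls <- lapply(r$calls, function(cl) {
      if (is_missing_call(cl)) "MISSING" else paste(cl$alleles, collapse = "/")
    })
    calls <- calls[order(names(calls))]
    preds <- lapply(r$predictions, function(p) {
      list(values = as.list(p$values), certainty = p$certainty,
           caveats = as.list(sort(p$caveats)), derivation = as.list(p$derivation))
    })
    preds <- preds[order(names(preds))]
    list(sample_id = r$sample_id, calls = calls, predictions = preds,
         identikit = r$identikit)
  })
  json <- jsonlite::toJSON(list(report = "dogphen", samples = samples),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  if (!is.null(summary_path)) {
    rows <- do.call(rbind, lapply(results, function(r) {
      data.frame(sample_id = r$sample_id,
                 trait = names(r$predictions),
                 value = vapply(r$predictions, function(p)
                   paste(p$values, collapse = "|"), ""),
                 certainty = vapply(r$predictions, `[[`, "", "certainty"),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    write.table(rows, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-read a prediction report
#' @param path JSON report written by [write_report()].
#' @return Parsed report structure (nested lists).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
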