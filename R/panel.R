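#' Path to the bundled 21-marker canine panel file
#'
#' @return Path to the YAML panel definition shipped with the package.
#' @export
default_panel_path <- function() {
  system.file("extdata", "panel_canine_21.yaml", package = "dogphen", mustWork = TRUE)
}

# trait categories and loci recognised by the model
trait_categories <- function() {
  c("coat_colour", "coat_pattern", "coat_structure", "tail_length",
    "ear_shape", "body_size")
}

marker_types <- function() c("SNP", "microINDEL", "intermediate_INDEL", "SINE")

dominance_levels <- function() c("dominant", "recessive", "semi_dominant", "unclarified")

# markers the inference rules name; a panel lacking any of these is rejected
required_markers <- function() {
  c("MC1R_306ter", "MC1R_M264V", "CBD103_S54", "CBD103_S53",
    "ASIP_S82", "ASIP_H83", "ASIP_SINE", "ASIP_R96",
    "TYRP1_Q331ter", "TYRP1_345delP", "MLPH_157471_c.-22G>A",
    "MITF_SNP", "MITF_INS", "PMEL", "PSMB7",
    "FGF5", "RSPO2", "KRT71", "T-Box_C295G", "BICFPJ1062878", "IGF1R")
}

#' Load and validate a marker panel
#'
#' Reads a YAML panel definition (one record per marker: locus, trait
#' category, marker type, alleles with nucleotide states and dominance
#' annotations, optional CanFam3.1 coordinate) together with its companion
#' FASTA of reference contexts, and validates the model. Structural rules
#' are enforced for any panel (unique marker ids, at least two alleles per
#' marker with pairwise-distinct states, known trait categories, marker
#' types and dominance tokens); in addition every marker named by the
#' inference rules must be present, so that user-extended panels remain
#' usable while accidental deletions are caught by name.
#'
#' @param path Panel YAML file; defaults to the bundled canine-21 panel.
#' @return An object of class `dog_panel`: a list with `version`,
#'   `locus_order`, `contexts_fasta` and `markers` (named list). Each
#'   marker carries its allele table (`name`, `state`, `dominance`,
#'   `phenotype`) and, where available, reference context sequences
#'   (`contexts$context` for SNPs; `contexts$short` / `contexts$long` for
#'   insertion markers).
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) stop_dogphen("panel file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$markers)) stop_dogphen("panel file has no 'markers' section: ", path)

  contexts <- list()
  fasta_name <- raw$contexts_fasta %||% NA_character_
  if (!is.na(fasta_name)) {
    fasta_path <- file.path(dirname(path), fasta_name)
    if (file.exists(fasta_path)) {
      seqs <- Biostrings::readDNAStringSet(fasta_path)
      contexts <- setNames(as.character(seqs), names(seqs))
    }
  }

  markers <- lapply(raw$markers, function(m) {
    al <- do.call(rbind, lapply(m$alleles, function(a) {
      data.frame(name = a$name, state = a$state,
                 dominance = a$dominance, phenotype = a$phenotype %||% "",
                 stringsAsFactors = FALSE)
    }))
    ctx <- list()
    if (identical(m$marker_type, "SNP")) {
      key <- paste0(m$marker_id, "|context")
      if (key %in% names(contexts)) ctx$context <- unname(contexts[[key]])
    } else {
      ks <- paste0(m$marker_id, "|short"); kl <- paste0(m$marker_id, "|long")
      if (ks %in% names(contexts)) ctx$short <- unname(contexts[[ks]])
      if (kl %in% names(contexts)) ctx$long <- unname(contexts[[kl]])
    }
    structure(list(
      marker_id = m$marker_id,
      locus = m$locus,
      trait_category = m$trait_category,
      marker_type = m$marker_type,
      chrom = m$chrom %||% NA_character_,
      pos = m$pos %||% NA_integer_,
      variant_offset = m$variant_offset %||% NA_integer_,
      long_allele = m$long_allele %||% NA_character_,
      alleles = al,
      contexts = ctx
    ), class = "dog_marker")
  })
  ids <- vapply(markers, `[[`, "", "marker_id")
  names(markers) <- ids

  panel <- structure(list(
    version = raw$version %||% "",
    locus_order = unlist(raw$locus_order),
    contexts_fasta = fasta_name,
    markers = markers
  ), class = "dog_panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  ids <- names(panel$markers)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_dogphen("duplicate marker_id in panel: ", paste(dup, collapse = ", "),
                                class = "dogphen_panel_error")
  for (m in panel$markers) {
    if (nrow(m$alleles) < 2)
      stop_dogphen("marker ", m$marker_id, " defines fewer than two alleles",
                   class = "dogphen_panel_error")
    if (anyDuplicated(m$alleles$state))
      stop_dogphen("marker ", m$marker_id, ": allele states are not pairwise distinct",
                   class = "dogphen_panel_error")
    if (anyDuplicated(m$alleles$name))
      stop_dogphen("marker ", m$marker_id, ": allele symbols are not distinct",
                   class = "dogphen_panel_error")
    if (any(!nzchar(m$alleles$state)))
      stop_dogphen("marker ", m$marker_id, ": empty allele state",
                   class = "dogphen_panel_error")
    if (!m$trait_category %in% trait_categories())
      stop_dogphen("marker ", m$marker_id, ": unknown trait_category '",
                   m$trait_category, "'", class = "dogphen_panel_error")
    if (!m$marker_type %in% marker_types())
      stop_dogphen("marker ", m$marker_id, ": unknown marker_type '",
                   m$marker_type, "'", class = "dogphen_panel_error")
    if (any(!m$alleles$dominance %in% dominance_levels()))
      stop_dogphen("marker ", m$marker_id, ": unknown dominance token",
                   class = "dogphen_panel_error")
    if (m$marker_type != "SNP" &&
        (is.na(m$long_allele) || !m$long_allele %in% m$alleles$name))
      stop_dogphen("marker ", m$marker_id,
                   ": insertion marker must name its insertion-bearing allele (long_allele)",
                   class = "dogphen_panel_error")
  }
  missing <- setdiff(required_markers(), ids)
  if (length(missing))
    stop_dogphen("panel is missing required marker(s): ",
                 paste(missing, collapse = ", "), class = "dogphen_panel_error")
  lo <- panel$locus_order
  if (!all(c("E", "K", "A") %in% lo) ||
      !(match("E", lo) < match("K", lo) && match("K", lo) < match("A", lo)))
    stop_dogphen("locus_order must contain E before K before A",
                 class = "dogphen_panel_error")
  invisible(panel)
}

#' Look up a marker by id
#'
#' @param panel A `dog_panel`.
#' @param marker_id Marker identifier as in the panel file.
#' @return The `dog_marker` record.
#' @export
marker_by_id <- function(panel, marker_id) {
  m <- panel$markers[[marker_id]]
  if (is.null(m)) stop_dogphen("unknown marker_id: ", marker_id,
                               class = "dogphen_lookup_error")
  m
}

#' Write a panel back to disk
#'
#' Serializes a `dog_panel` to the same YAML dialect read by
#' [load_panel()], and writes the companion context FASTA next to it, so
#' that a written panel re-loads to an identical model.
#'
#' @param panel A `dog_panel`.
#' @param path Output YAML path; the FASTA is written to the file named by
#'   `panel$contexts_fasta` in the same directory.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  mk <- lapply(unname(panel$markers), function(m) {
    rec <- list(marker_id = m$marker_id, locus = m$locus,
                trait_category = m$trait_category, marker_type = m$marker_type)
    if (!is.na(m$chrom)) rec$chrom <- m$chrom
    if (!is.na(m$pos)) rec$pos <- m$pos
    if (!is.na(m$variant_offset)) rec$variant_offset <- m$variant_offset
    if (!is.na(m$long_allele)) rec$long_allele <- m$long_allele
    rec$alleles <- lapply(seq_len(nrow(m$alleles)), function(i) {
      as.list(m$alleles[i, c("name", "state", "dominance", "phenotype")])
    })
    rec
  })
  out <- list(version = panel$version,
              locus_order = as.list(panel$locus_order),
              contexts_fasta = panel$contexts_fasta,
              markers = mk)
  yaml::write_yaml(out, path)
  if (!is.na(panel$contexts_fasta)) {
    lines <- character(0)
    for (m in panel$markers) {
      for (kind in names(m$contexts)) {
        lines <- c(lines, paste0(">", m$marker_id, "|", kind), m$contexts[[kind]])
      }
    }
    writeLines(lines, file.path(dirname(path), panel$contexts_fasta))
  }
  invisible(path)
}

#' @export
print.dog_panel <- function(x, ...) {
  types <- vapply(x$markers, `[[`, "", "marker_type")
  cat("dog_panel '", x$version, "': ", length(x$markers), " markers (",
      sum(types == "SNP"), " SNP, ", sum(types != "SNP"), " INDEL-type of which ",
      sum(types == "SINE"), " SINE)\n", sep = "")
  cat("locus order:", paste(x$locus_order, collapse = " > "), "\n")
  invisible(x)
}
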