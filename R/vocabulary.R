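#' Controlled phenotype vocabulary
#'
#' The standardized trait states used for both predictions and observed
#' phenotype records. Coat pattern and coat structure values are composite
#' tokens: ordered components joined with `"+"` (e.g.
#' `"tan_points+minimal_white"`, `"long+smooth+no_furnishings"`).
#'
#' @return Named list: for single-valued traits the allowed tokens, for
#'   composite traits the allowed components per axis.
#' @export
trait_vocabulary <- function() {
  list(
    coat_colour = c("red_yellow_cream", "pale_cream", "fawn_sable", "agouti",
                    "black", "brown", "blue", "isabella"),
    coat_pattern = list(
      overlay_pre = "tan_points",
      spotting = c("minimal_white", "pseudo_irish", "piebald"),
      merle = c("merle", "mainly_white"),
      overlay_post = "harlequin"
    ),
    coat_structure = list(
      length = c("short", "long"),
      curl = c("smooth", "wavy", "curly"),
      furnishings = c("furnishings", "no_furnishings")
    ),
    tail_length = c("long_tail", "bobtail"),
    ear_shape = c("drop", "non_drop"),
    body_size = c("rather_small", "rather_tall")
  )
}

#' Caveat codes attached to trait predictions
#'
#' @return Character vector of the documented caveat codes.
#' @export
caveat_codes <- function() {
  c("possible_brindle", "possible_docking", "possible_cropping",
    "untested_allele_bc", "hidden_merle", "lethal_genotype_observed",
    "mask_not_visible_on_solid", "possible_ancestral_bobtail")
}

# Canonical composition of a coat-pattern value from its components.
# Order: tan_points, spotting level, merle layer, harlequin.
compose_pattern <- function(tan_points = FALSE,
                            spotting = "minimal_white",
                            merle = "none",
                            harlequin = FALSE) {
  parts <- character(0)
  if (isTRUE(tan_points)) parts <- c(parts, "tan_points")
  parts <- c(parts, spotting)
  if (merle != "none") parts <- c(parts, merle)
  if (isTRUE(harlequin)) parts <- c(parts, "harlequin")
  paste(parts, collapse = "+")
}

compose_structure <- function(length_ = "?", curl = "?", furnishings = "?") {
  paste(c(length_, curl, furnishings), collapse = "+")
}

# validate an observed value against the vocabulary; TRUE or a message
check_vocab_value <- function(trait, value) {
  voc <- trait_vocabulary()[[trait]]
  if (is.null(voc)) return(paste0("unknown trait category '", trait, "'"))
  if (trait == "coat_pattern") {
    comp <- strsplit(value, "+", fixed = TRUE)[[1]]
    allowed <- c(voc$overlay_pre, voc$spotting, voc$merle, voc$overlay_post)
    bad <- setdiff(comp, allowed)
    if (length(bad)) return(paste0("coat_pattern component(s) outside vocabulary: ",
                                   paste(bad, collapse = ", ")))
    if (sum(comp %in% voc$spotting) != 1)
      return("coat_pattern must contain exactly one spotting component")
    return(TRUE)
  }
  if (trait == "coat_structure") {
    comp <- strsplit(value, "+", fixed = TRUE)[[1]]
    if (length(comp) != 3 || !comp[1] %in% voc$length || !comp[2] %in% voc$curl ||
        !comp[3] %in% voc$furnishings)
      return(paste0("coat_structure value '", value,
                    "' is not 'length+curl+furnishings' from the vocabulary"))
    return(TRUE)
  }
  if (!value %in% voc)
    return(paste0(trait, " value '", value, "' outside controlled vocabulary"))
  TRUE
}
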