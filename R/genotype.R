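# Genotype calls and profiles.
#
# A call is an unordered allele pair at one marker, stored order-normalized
# (canonical order = order of the allele table in the panel) so that
# heterozygotes compare equal regardless of input order. MISSING is a
# first-class state: failed sequencing must be carried through the pipeline,
# not dropped.

#' Construct a genotype call from allele symbols
#'
#' @param panel A `dog_panel`.
#' @param marker_id Marker identifier.
#' @param alleles Character vector of length 2 of allele symbols defined
#'   for the marker, or `NULL` for a MISSING call.
#' @return A `dog_call`: list with `marker_id`, `alleles` (canonically
#'   ordered, or `NULL`), `raw_states`, `conflict`.
#' @export
genotype_call <- function(panel, marker_id, alleles = NULL) {
  m <- marker_by_id(panel, marker_id)
  if (is.null(alleles) || all(is.na(alleles))) {
    return(structure(list(marker_id = marker_id, alleles = NULL,
                          raw_states = NULL, conflict = FALSE),
                     class = "dog_call"))
  }
  if (length(alleles) != 2)
    stop_dogphen("marker ", marker_id, ": a call needs exactly two alleles")
  idx <- match(alleles, m$alleles$name)
  if (anyNA(idx))
    stop_dogphen("marker ", marker_id, ": unknown allele symbol(s) ",
                 paste(alleles[is.na(idx)], collapse = ", "),
                 class = "dogphen_allele_error")
  idx <- sort(idx)
  structure(list(marker_id = marker_id,
                 alleles = m$alleles$name[idx],
                 raw_states = m$alleles$state[idx],
                 conflict = FALSE),
            class = "dog_call")
}

# build a call from observed nucleotide/presence states
call_from_states <- function(panel, marker_id, states) {
  m <- marker_by_id(panel, marker_id)
  if (is.null(states) || all(is.na(states)) || all(!nzchar(states)))
    return(genotype_call(panel, marker_id, NULL))
  idx <- match(states, m$alleles$state)
  if (anyNA(idx)) {
    # fall back: states given as allele symbols
    idx2 <- match(states, m$alleles$name)
    if (anyNA(idx2))
      stop_dogphen("marker ", marker_id, ": state(s) ",
                   paste(states[is.na(idx)], collapse = ", "),
                   " match no defined allele", class = "dogphen_allele_error")
    idx <- idx2
  }
  genotype_call(panel, marker_id, m$alleles$name[idx])
}

is_missing_call <- function(call) is.null(call$alleles)

# number of copies of `allele` in the call; NA if the call is missing
allele_count <- function(profile, marker_id, allele) {
  call <- profile$calls[[marker_id]]
  if (is.null(call) || is_missing_call(call)) return(NA_integer_)
  sum(call$alleles == allele)
}

#' Construct a genotype profile
#'
#' One sample's calls across the full panel; every panel marker gets a call
#' slot (MISSING allowed, and filled in for markers not supplied).
#'
#' @param sample_id Non-empty alphanumeric sample identifier.
#' @param calls Named list of `dog_call` objects (names = marker ids).
#' @param panel A `dog_panel`.
#' @return A `dog_profile`.
#' @export
genotype_profile <- function(sample_id, calls, panel) {
  if (!nzchar(sample_id)) stop_dogphen("sample_id must be non-empty")
  unknown <- setdiff(names(calls), names(panel$markers))
  if (length(unknown))
    stop_dogphen("sample ", sample_id, ": calls for unknown marker(s) ",
                 paste(unknown, collapse = ", "))
  full <- setNames(vector("list", length(panel$markers)), names(panel$markers))
  for (id in names(panel$markers)) {
    full[[id]] <- calls[[id]] %||% genotype_call(panel, id, NULL)
  }
  structure(list(sample_id = sample_id, calls = full), class = "dog_profile")
}

# fixture/simulator helper: profile from a named list of state pairs;
# entries set to NA give MISSING calls, unspecified markers take `base`
profile_from_states <- function(panel, sample_id, states, base = NULL) {
  all_states <- base %||% list()
  for (id in names(states)) all_states[[id]] <- states[[id]]
  calls <- list()
  for (id in names(all_states)) {
    st <- all_states[[id]]
    calls[[id]] <- if (all(is.na(st))) genotype_call(panel, id, NULL)
                   else call_from_states(panel, id, st)
  }
  genotype_profile(sample_id, calls, panel)
}

#' @export
print.dog_profile <- function(x, ...) {
  miss <- sum(vapply(x$calls, is_missing_call, TRUE))
  cat("dog_profile ", x$sample_id, ": ", length(x$calls) - miss, "/",
      length(x$calls), " markers called\n", sep = "")
  invisible(x)
}

#' @export
format.dog_call <- function(x, ...) {
  if (is_missing_call(x)) "MISSING" else paste(x$alleles, collapse = "/")
}
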