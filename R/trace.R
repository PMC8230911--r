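# Sanger-style base-call traces.
#
# A trace is the pair of primary and secondary base-call strings read off a
# chromatogram: `primary` over {A,C,G,T,N}, `secondary` of equal length over
# {A,C,G,T,-} where "-" means no secondary peak. Together they encode IUPAC
# mixtures at heterozygous positions. When a short (no-insertion) and a long
# (insertion-bearing) amplicon co-amplify in a heterozygote, the two
# sequences run out of phase downstream of the insertion point and the
# trace shows their superposition; resolve_superposition() classifies such
# traces by reading the overlapping calls position by position.

#' Construct a trace read
#'
#' @param marker_id Marker the trace covers.
#' @param primary Primary base-call string (`A,C,G,T,N`).
#' @param secondary Secondary base-call string of equal length
#'   (`A,C,G,T,-`; `-` = no secondary peak). A secondary call must differ
#'   from the primary call at the same position.
#' @param orientation `"forward"` or `"reverse"` relative to the marker's
#'   reference context.
#' @return A `dog_trace`.
#' @export
trace_read <- function(marker_id, primary, secondary = NULL,
                       orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (is.null(secondary)) secondary <- strrep("-", nchar(primary))
  if (nchar(primary) != nchar(secondary))
    stop_dogphen("primary and secondary strings must have equal length")
  if (grepl("[^ACGTN]", primary))
    stop_dogphen("primary contains characters outside {A,C,G,T,N}")
  if (grepl("[^ACGT-]", secondary))
    stop_dogphen("secondary contains characters outside {A,C,G,T,-}")
  p <- chars(primary); s <- chars(secondary)
  clash <- s != "-" & s == p
  if (any(clash))
    stop_dogphen("secondary call equals primary call at position(s) ",
                 paste(which(clash), collapse = ", "))
  structure(list(marker_id = marker_id, primary = primary,
                 secondary = secondary, orientation = orientation),
            class = "dog_trace")
}

# return the trace in forward orientation
orient_trace <- function(trace) {
  if (trace$orientation == "forward") return(trace)
  trace_read(trace$marker_id,
             revcomp_calls(trace$primary),
             revcomp_calls(trace$secondary),
             orientation = "forward")
}

#' Read a trace table
#'
#' TSV with columns `sample_id`, `marker_id`, `orientation`, `primary`,
#' `secondary` (empty secondary means no secondary peaks anywhere).
#'
#' @param path TSV file.
#' @return Named list (by sample) of lists of `dog_trace`.
#' @export
read_trace_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "marker_id", "orientation", "primary", "secondary")
  if (!all(need %in% names(tab)))
    stop_dogphen("trace table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    sec <- tab$secondary[i]
    if (is.na(sec) || !nzchar(sec)) sec <- NULL
    tr <- trace_read(tab$marker_id[i], tab$primary[i], sec, tab$orientation[i])
    out[[tab$sample_id[i]]] <- c(out[[tab$sample_id[i]]], list(tr))
  }
  out
}

# divergence point: first position where short and long allele sequences
# differ (left alignment; when the inserted block begins with the same base
# as the sequence following the insertion site, this automatically shifts
# the divergence point right to the first true mismatch)
divergence_point <- function(short_allele, long_allele) {
  s <- chars(short_allele); l <- chars(long_allele)
  blen <- length(l) - length(s)
  if (blen < 1)
    stop_dogphen("long_allele must be longer than short_allele")
  n <- length(s)
  d <- n + 1L
  for (i in seq_len(n)) {
    if (s[i] != l[i]) { d <- i; break }
  }
  # precondition: long = short with one inserted block
  if (d <= n && !identical(l[(d + blen):length(l)], s[d:n]))
    stop_dogphen("long_allele is not short_allele with a single inserted block")
  d
}

#' Classify a trace over a short/long allele pair
#'
#' Implements the base-call-level interpretation of out-of-phase
#' heterozygous insertion traces. The divergence point is located by exact
#' prefix match of the two allele sequences; upstream of it the trace must
#' match the common prefix with no secondary peaks. Downstream, under
#' heterozygosity, each position is expected to show the multiset of bases
#' contributed by the short and the long allele aligned at that position
#' (a single clean call where the two alignments agree, a primary+secondary
#' pair where they differ); a homozygous trace must match one allele with
#' no secondary peaks. Anything else is `inconsistent`. Mismatch tolerance
#' defaults to 0: forensic use favours failing loudly.
#'
#' @param trace A `dog_trace` (aligned so that position 1 of the trace is
#'   position 1 of the allele sequences; reverse traces are
#'   reverse-complemented first).
#' @param short_allele,long_allele The two allele sequences; `long_allele`
#'   must equal `short_allele` with one inserted block.
#' @param tolerance Number of positions allowed to violate the expectation
#'   for a classification to stand (default 0).
#' @param min_window Minimum number of evaluable positions at or after the
#'   divergence point (default 15); shorter traces return `"insufficient"`.
#' @return One of `"hom_short"`, `"hom_long"`, `"het"`, `"inconsistent"`,
#'   `"insufficient"`.
#' @export
resolve_superposition <- function(trace, short_allele, long_allele,
                                  tolerance = 0, min_window = 15) {
  trace <- orient_trace(trace)
  d <- divergence_point(short_allele, long_allele)
  p <- chars(trace$primary); s <- chars(trace$secondary)
  n <- length(p)
  if (n - d + 1L < min_window) return("insufficient")

  sh <- chars(short_allele); lo <- chars(long_allele)
  mism_hom <- function(al) {
    bad <- 0L
    for (i in seq_len(n)) {
      ok <- i <= length(al) && p[i] == al[i] && s[i] == "-"
      if (!ok) bad <- bad + 1L
    }
    bad
  }
  mism_het <- function() {
    bad <- 0L
    for (i in seq_len(n)) {
      exp <- unique(c(if (i <= length(sh)) sh[i], if (i <= length(lo)) lo[i]))
      obs <- c(p[i], if (s[i] != "-") s[i])
      if (length(exp) == 0L || !setequal(obs, exp)) bad <- bad + 1L
    }
    bad
  }
  if (mism_hom(sh) <= tolerance) return("hom_short")
  if (mism_hom(lo) <= tolerance) return("hom_long")
  if (mism_het() <= tolerance) return("het")
  "inconsistent"
}

#' Call a point variant (SNP or 3-bp microINDEL) from a trace
#'
#' For SNPs the trace is anchored to the marker's reference context by
#' exact flank match around the variant site (`anchor` bases each side,
#' with no secondary peaks inside the anchors); a primary-only call gives a
#' homozygote, a primary+secondary pair matching both allele states a
#' heterozygote. MicroINDELs are dispatched to [resolve_superposition()]
#' over the marker's short/long contexts. Returns a MISSING call when the
#' anchors fail or the read is insufficient.
#'
#' @param trace A `dog_trace`.
#' @param marker A `dog_marker` (SNP or microINDEL).
#' @param panel A `dog_panel` (for call construction).
#' @param anchor Anchor length each side of the variant site (default 10).
#' @param tolerance,min_window Passed to [resolve_superposition()] for
#'   microINDELs.
#' @return A `dog_call`; observed bases matching no defined allele raise an
#'   "unrecognized allele" error carrying the observed states.
#' @export
call_point_variant <- function(trace, marker, panel, anchor = 10,
                               tolerance = 0, min_window = 15) {
  if (!marker$marker_type %in% c("SNP", "microINDEL"))
    stop_dogphen("call_point_variant handles SNP and microINDEL markers only")
  if (marker$marker_type == "microINDEL")
    return(call_superposed(trace, marker, panel, anchor, tolerance, min_window))

  trace <- orient_trace(trace)
  ctx <- marker$contexts$context
  if (is.null(ctx)) stop_dogphen("marker ", marker$marker_id, " has no reference context")
  off <- marker$variant_offset
  left <- substr(ctx, off - anchor, off - 1)
  right <- substr(ctx, off + 1, off + anchor)
  hit <- regexpr(left, trace$primary, fixed = TRUE)
  if (hit < 0) return(genotype_call(panel, marker$marker_id, NULL))
  site <- hit + anchor
  if (substr(trace$primary, site + 1, site + anchor) != right)
    return(genotype_call(panel, marker$marker_id, NULL))
  anch_sec <- paste0(substr(trace$secondary, hit, site - 1),
                     substr(trace$secondary, site + 1, site + anchor))
  if (grepl("[^-]", anch_sec))
    return(genotype_call(panel, marker$marker_id, NULL))
  pb <- substr(trace$primary, site, site)
  sb <- substr(trace$secondary, site, site)
  if (pb == "N") return(genotype_call(panel, marker$marker_id, NULL))
  obs <- if (sb == "-") c(pb, pb) else c(pb, sb)
  idx <- match(obs, marker$alleles$state)
  if (anyNA(idx))
    stop_dogphen("marker ", marker$marker_id, ": unrecognized allele state(s) ",
                 paste(unique(obs[is.na(idx)]), collapse = ", "),
                 class = "dogphen_allele_error")
  genotype_call(panel, marker$marker_id, marker$alleles$name[idx])
}

# superposition-based call for microINDEL / SINE / intermediate insertions
call_superposed <- function(trace, marker, panel, anchor = 10,
                            tolerance = 0, min_window = 15) {
  short <- marker$contexts$short; long <- marker$contexts$long
  if (is.null(short) || is.null(long))
    stop_dogphen("marker ", marker$marker_id, " has no short/long reference contexts")
  trace <- orient_trace(trace)
  # crop the trace to start at the context origin using a prefix anchor
  d <- divergence_point(short, long)
  pre <- substr(short, 1, min(anchor, d - 1))
  start <- if (nzchar(pre)) regexpr(pre, trace$primary, fixed = TRUE) else 1L
  if (start < 0) return(genotype_call(panel, marker$marker_id, NULL))
  cropped <- trace_read(marker$marker_id,
                        substr(trace$primary, start, nchar(trace$primary)),
                        substr(trace$secondary, start, nchar(trace$secondary)))
  z <- resolve_superposition(cropped, short, long, tolerance, min_window)
  long_al <- marker$long_allele
  short_al <- setdiff(marker$alleles$name, long_al)[1]
  switch(z,
    hom_short = genotype_call(panel, marker$marker_id, c(short_al, short_al)),
    hom_long = genotype_call(panel, marker$marker_id, c(long_al, long_al)),
    het = genotype_call(panel, marker$marker_id, c(short_al, long_al)),
    insufficient = genotype_call(panel, marker$marker_id, NULL),
    stop_dogphen("marker ", marker$marker_id,
                 ": trace is inconsistent with every zygosity at tolerance ",
                 tolerance, class = "dogphen_allele_error")
  )
}

#' Call a full genotype profile from traces
#'
#' Dispatches each trace to the appropriate caller by marker type (SNPs and
#' microINDELs to [call_point_variant()], SINE and intermediate insertions
#' to the superposition caller). Markers without a trace become MISSING.
#' Per-marker errors are collected, never aborting the sample; they are
#' attached as attribute `"call_errors"` and raised as a single warning.
#'
#' @param traces List of `dog_trace` (at most one per marker).
#' @param panel A `dog_panel`.
#' @param sample_id Sample identifier for the resulting profile.
#' @return A `dog_profile`.
#' @export
call_profile <- function(traces, panel, sample_id) {
  ids <- vapply(traces, `[[`, "", "marker_id")
  if (anyDuplicated(ids))
    stop_dogphen("more than one trace for marker(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  calls <- list()
  errors <- character(0)
  for (tr in traces) {
    m <- marker_by_id(panel, tr$marker_id)
    res <- tryCatch({
      if (m$marker_type %in% c("SNP", "microINDEL"))
        call_point_variant(tr, m, panel)
      else
        call_superposed(tr, m, panel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(m$marker_id, ": ", conditionMessage(res)))
      calls[[m$marker_id]] <- genotype_call(panel, m$marker_id, NULL)
    } else {
      calls[[m$marker_id]] <- res
    }
  }
  if (length(errors))
    warning("sample ", sample_id, ": ", length(errors), " marker(s) failed: ",
            paste(errors, collapse = "; "))
  prof <- genotype_profile(sample_id, calls, panel)
  attr(prof, "call_errors") <- errors
  prof
}

#' Build the ideal trace for a genotype
#'
#' Constructs the clean base-call trace a Sanger run would produce for a
#' given genotype at a marker: a single sequence with no secondary peaks
#' for homozygotes, the exact superposition of the two allele sequences for
#' heterozygous insertion markers, and a secondary peak at the variant site
#' for heterozygous SNPs. Used by the simulator and as a test harness.
#'
#' @param marker A `dog_marker`.
#' @param alleles Character vector of length 2 of allele symbols.
#' @param orientation Orientation of the produced trace.
#' @return A `dog_trace`.
#' @export
ideal_trace <- function(marker, alleles, orientation = "forward") {
  if (marker$marker_type == "SNP") {
    ctx <- marker$contexts$context
    off <- marker$variant_offset
    states <- marker$alleles$state[match(alleles, marker$alleles$name)]
    primary <- ctx
    substr(primary, off, off) <- states[1]
    secondary <- strrep("-", nchar(ctx))
    if (states[1] != states[2]) substr(secondary, off, off) <- states[2]
    tr <- trace_read(marker$marker_id, primary, secondary)
  } else {
    long_al <- marker$long_allele
    n_long <- sum(alleles == long_al)
    seqs <- list(short = marker$contexts$short, long = marker$contexts$long)
    tr <- if (n_long == 0) {
      trace_read(marker$marker_id, seqs$short)
    } else if (n_long == 2) {
      trace_read(marker$marker_id, seqs$long)
    } else {
      sp <- superpose_sequences(seqs$short, seqs$long)
      trace_read(marker$marker_id, sp$primary, sp$secondary)
    }
  }
  if (orientation == "reverse")
    tr <- trace_read(marker$marker_id, revcomp_calls(tr$primary),
                     revcomp_calls(tr$secondary), orientation = "reverse")
  tr
}

# exact superposition of two co-amplified sequences, read to the end of the
# longer one; primary carries the long allele's base where the two differ
superpose_sequences <- function(short_allele, long_allele) {
  sh <- chars(short_allele); lo <- chars(long_allele)
  n <- length(lo)
  p <- character(n); s <- rep("-", n)
  for (i in seq_len(n)) {
    a <- if (i <= length(sh)) sh[i] else NA
    b <- lo[i]
    p[i] <- b
    if (!is.na(a) && a != b) s[i] <- a
  }
  list(primary = paste(p, collapse = ""), secondary = paste(s, collapse = ""))
}
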