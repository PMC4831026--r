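#' Match observed peaks against a marker panel
#'
#' For each taxon, each marker slot is matched to the nearest observed peak
#' within `tolerance`. Matching is per slot, not bag-of-masses: within one
#' taxon a peak can satisfy at most one slot (when a peak is the nearest
#' candidate for two slots, slots are resolved by maximum assignment with
#' preference for smaller |delta|, then higher intensity). The same peak may
#' satisfy the homologous slot of several taxa.
#'
#' @param spectrum A centroid `maldi_spectrum` (quality-gated spectra are
#'   recommended but not enforced).
#' @param panel A [marker_panel()].
#' @param tolerance Maximum |observed - reference| in Da (default 0.5, the
#'   conventional fingerprint search tolerance).
#' @return A tibble with one row per taxon and slot: `taxon`, `rank`,
#'   `genus`, `slot`, `reference_mz`, `observed_mz`, `intensity`, `delta`,
#'   `matched`.
#' @export
match_markers <- function(spectrum, panel, tolerance = 0.5) {
  assert_spectrum(spectrum, mode = "centroid")
  stopifnot(inherits(panel, "marker_panel"))
  if (tolerance <= 0) abort("`tolerance` must be positive")
  long <- panel_long(panel)
  mz <- spectrum$mz
  ity <- spectrum$intensity
  purrr::map_dfr(unique(long$taxon), function(tx) {
    rows <- long[long$taxon == tx, ]
    assignment <- assign_slots(rows$reference_mz, mz, ity, tolerance)
    rows$observed_mz <- ifelse(is.na(assignment), NA_real_, mz[assignment])
    rows$intensity <- ifelse(is.na(assignment), NA_real_, ity[assignment])
    rows$delta <- rows$observed_mz - rows$reference_mz
    rows$matched <- !is.na(assignment)
    rows
  })
}

# Maximum bipartite assignment of slots to peaks under the tolerance
# constraint, preferring smaller |delta| then higher intensity. Augmenting
# paths guarantee that widening the tolerance can never lose a match.
assign_slots <- function(refs, mz, intensity, tolerance) {
  n_slot <- length(refs)
  out <- rep(NA_integer_, n_slot)
  if (length(mz) == 0) return(out)
  cand <- lapply(refs, function(r) {
    d <- abs(mz - r)
    i <- which(d <= tolerance)
    i[order(d[i], -intensity[i], i)]
  })
  slot_of_peak <- new.env(parent = emptyenv())
  try_assign <- function(slot, visited) {
    for (p in cand[[slot]]) {
      key <- as.character(p)
      if (key %in% visited$seen) next
      visited$seen <- c(visited$seen, key)
      holder <- slot_of_peak[[key]]
      if (is.null(holder) || try_assign(holder, visited)) {
        slot_of_peak[[key]] <- slot
        return(TRUE)
      }
    }
    FALSE
  }
  # seed slots in order of their closest candidate so the unambiguous cases
  # keep their nearest peak
  best_d <- vapply(seq_len(n_slot), function(s) {
    if (length(cand[[s]]) == 0) Inf else abs(mz[cand[[s]][[1]]] - refs[[s]])
  }, numeric(1))
  for (s in order(best_d)) {
    if (length(cand[[s]]) > 0) {
      try_assign(s, visited = local({e <- new.env(); e$seen <- character(); e}))
    }
  }
  for (key in ls(slot_of_peak)) {
    out[slot_of_peak[[key]]] <- as.integer(key)
  }
  out
}

#' Assign a taxon to a fingerprint
#'
#' Candidate taxa are ranked by matched-slot count from [match_markers()].
#' The winner must match at least `min_markers` slots and lead the best
#' taxon from any *other* genus by at least `margin`. When the top candidates
#' are congeneric species tied on count, the call degrades to genus level.
#' A species-level call additionally requires that at least one matched slot
#' be diagnostic for that species (its reference value unique in the panel
#' column, e.g. slot 8 for the two *Rattus* species). With no supportable
#' candidate the verdict is `"indeterminate"`.
#'
#' Independently of the verdict, the spectrum is flagged as a *murine
#' candidate* when the panel's screening slot (the 1443.7 murine marker in
#' the bundled panel) is matched while its conserved vertebrate counterpart
#' (1459.7) is absent.
#'
#' @inheritParams match_markers
#' @param min_markers Minimum matched slots for any assignment (default 4).
#' @param margin Required lead (in slots) over the best taxon of any other
#'   genus (default 1).
#' @return An object of class `taxon_assignment` with fields `label`,
#'   `resolution` (`"species"`, `"genus"` or `"none"`), `matched` (tibble of
#'   matched slots), `score`, `ambiguity` (character vector of tied taxa),
#'   `murine_candidate`, and `scores` (per-taxon match counts).
#'   [tidy()] returns the matched slots, [glance()] a one-row summary.
#' @examples
#' panel <- default_panel()
#' peaks <- new_spectrum(
#'   data.frame(mz = unlist(panel$taxa[panel$taxa$taxon == "Apodemus",
#'                                     paste0("slot", 1:9)]),
#'              intensity = 10, snr = 20),
#'   mode = "centroid")
#' classify(peaks, panel)
#' @export
classify <- function(spectrum, panel, tolerance = 0.5, min_markers = 4,
                     margin = 1) {
  mm <- match_markers(spectrum, panel, tolerance)
  scores <- dplyr::summarise(
    dplyr::group_by(mm, .data$taxon, .data$rank, .data$genus),
    score = sum(.data$matched), .groups = "drop"
  )
  scores <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$taxon)

  murine <- murine_flag(spectrum, panel, tolerance)

  indeterminate <- function(ambiguity = character()) {
    new_taxon_assignment(
      label = "indeterminate", resolution = "none",
      matched = mm[0, ], score = 0L, ambiguity = ambiguity,
      murine_candidate = murine, scores = scores
    )
  }

  best <- scores$score[[1]]
  if (best < min_markers) return(indeterminate())
  top <- scores[scores$score == best, ]
  if (length(unique(top$genus)) > 1) {
    return(indeterminate(ambiguity = top$taxon))
  }
  other <- scores[scores$genus != top$genus[[1]], ]
  best_other <- if (nrow(other) == 0) -Inf else max(other$score)
  if (best - best_other < margin) {
    return(indeterminate(
      ambiguity = scores$taxon[scores$score > best - margin]
    ))
  }

  genus <- top$genus[[1]]
  if (nrow(top) > 1) {
    # congeneric species tied on count: genus-level call
    winner_matches <- mm[mm$taxon == top$taxon[[1]] & mm$matched, ]
    return(new_taxon_assignment(
      label = genus, resolution = "genus", matched = winner_matches,
      score = best, ambiguity = top$taxon, murine_candidate = murine,
      scores = scores
    ))
  }
  winner <- top$taxon[[1]]
  winner_matches <- mm[mm$taxon == winner & mm$matched, ]
  if (top$rank[[1]] == "genus") {
    return(new_taxon_assignment(
      label = winner, resolution = "genus", matched = winner_matches,
      score = best, ambiguity = character(), murine_candidate = murine,
      scores = scores
    ))
  }
  diag <- diagnostic_slots(panel, winner)
  if (any(winner_matches$slot %in% diag)) {
    new_taxon_assignment(
      label = winner, resolution = "species", matched = winner_matches,
      score = best, ambiguity = character(), murine_candidate = murine,
      scores = scores
    )
  } else {
    congeners <- panel$taxa$taxon[panel$taxa$genus == genus]
    new_taxon_assignment(
      label = genus, resolution = "genus", matched = winner_matches,
      score = best, ambiguity = setdiff(congeners, winner),
      murine_candidate = murine, scores = scores
    )
  }
}

# Screening-slot marker present while its conserved vertebrate counterpart
# is absent: the cheap first-pass test for a myomorph rodent fingerprint.
murine_flag <- function(spectrum, panel, tolerance) {
  if (is.na(panel$screen_slot) || is.na(panel$counterpart_mz)) return(NA)
  long <- panel_long(panel)
  ref <- unique(long$reference_mz[long$slot == panel$screen_slot])
  if (length(ref) != 1) return(NA)
  if (nrow(spectrum) == 0) return(FALSE)
  has_marker <- any(abs(spectrum$mz - ref) <= tolerance)
  has_counterpart <- any(abs(spectrum$mz - panel$counterpart_mz) <= tolerance)
  has_marker && !has_counterpart
}

new_taxon_assignment <- function(label, resolution, matched, score, ambiguity,
                                 murine_candidate, scores) {
  structure(
    list(label = label, resolution = resolution, matched = matched,
         score = as.integer(score), ambiguity = ambiguity,
         murine_candidate = murine_candidate, scores = scores),
    class = "taxon_assignment"
  )
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("<taxon_assignment> %s (%s), %d marker(s) matched%s%s\n",
              x$label, x$resolution, x$score,
              if (isTRUE(x$murine_candidate)) ", murine candidate" else "",
              if (length(x$ambiguity) > 0)
                paste0("; ambiguous among: ", paste(x$ambiguity, collapse = ", "))
              else ""))
  invisible(x)
}

#' @rdname classify
#' @param x A `taxon_assignment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.taxon_assignment <- function(x, ...) {
  as_tibble(x$matched)
}

#' @rdname classify
#' @exportS3Method generics::glance
glance.taxon_assignment <- function(x, ...) {
  tibble(
    label = x$label,
    resolution = x$resolution,
    score = x$score,
    murine_candidate = x$murine_candidate,
    n_ambiguous = length(x$ambiguity)
  )
}
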