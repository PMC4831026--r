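#' Construct a taxon-by-marker reference panel
#'
#' A marker panel is a table of reference \[M+H\]+ values: one row per taxon,
#' one column per marker slot. Slots are homologous peptide positions across
#' taxa -- some conserved across the whole panel, some diagnostic at genus
#' level, some separating congeneric species. Slot resolution is derived from
#' the column structure: a slot is `conserved` when all taxa share its value,
#' `species` when two species of the same genus differ in it, and `genus`
#' otherwise.
#'
#' @param taxa A data frame with columns `taxon`, `rank` (`"species"` or
#'   `"genus"`), `genus`, and numeric slot columns named `slot1`, `slot2`,
#'   ... Every taxon must have a value in every slot.
#' @param legacy_letters Optional character vector (one per slot) of marker
#'   letters used in earlier collagen-fingerprinting work, `NA` where none.
#' @param screen_slot Index of the slot used by the murine screening flag
#'   (the marker whose panel value replaces a conserved vertebrate mass).
#' @param counterpart_mz The conserved vertebrate counterpart m/z of the
#'   screening slot (default 1459.7, the near-universal vertebrate homologue
#'   of the 1443.7 murine marker).
#' @return An object of class `marker_panel` with elements `taxa` (tibble)
#'   and `slots` (tibble of slot descriptors).
#' @seealso [load_panel()], [default_panel()]
#' @export
marker_panel <- function(taxa, legacy_letters = NULL, screen_slot = NULL,
                         counterpart_mz = 1459.7) {
  taxa <- as_tibble(taxa)
  need <- c("taxon", "rank", "genus")
  missing <- setdiff(need, names(taxa))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  slot_cols <- grep("^slot[0-9]+$", names(taxa), value = TRUE)
  if (length(slot_cols) == 0) abort("panel has no slot columns (slot1, slot2, ...)")
  slot_cols <- slot_cols[order(as.integer(sub("^slot", "", slot_cols)))]
  if (nrow(taxa) == 0) abort("panel has no taxa")
  if (anyDuplicated(taxa$taxon)) {
    abort(sprintf("duplicate taxon name in panel: '%s'",
                  taxa$taxon[duplicated(taxa$taxon)][[1]]))
  }
  if (!all(taxa$rank %in% c("species", "genus"))) {
    abort("taxon rank must be 'species' or 'genus'")
  }
  for (sc in slot_cols) {
    vals <- taxa[[sc]]
    if (!is.numeric(vals)) abort(sprintf("slot column '%s' must be numeric", sc))
    if (any(is.na(vals))) {
      abort(sprintf("missing marker value for taxon '%s' in %s",
                    taxa$taxon[which(is.na(vals))[[1]]], sc))
    }
  }
  # congeneric species must be separable somewhere, else they should be
  # collapsed into a single genus-level row
  sp <- taxa[taxa$rank == "species", ]
  for (g in unique(sp$genus)) {
    rows <- sp[sp$genus == g, ]
    if (nrow(rows) > 1) {
      pairs <- utils::combn(seq_len(nrow(rows)), 2, simplify = FALSE)
      for (pr in pairs) {
        if (all(unlist(rows[pr[[1]], slot_cols]) ==
                unlist(rows[pr[[2]], slot_cols]))) {
          abort(sprintf(
            "species '%s' and '%s' are identical in every slot; collapse them to a genus-level row",
            rows$taxon[[pr[[1]]]], rows$taxon[[pr[[2]]]]
          ))
        }
      }
    }
  }
  slots <- tibble(
    slot = as.integer(sub("^slot", "", slot_cols)),
    column = slot_cols,
    legacy = if (is.null(legacy_letters)) NA_character_
             else rep_len(legacy_letters, length(slot_cols)),
    resolution = unname(vapply(slot_cols, function(sc) {
      vals <- taxa[[sc]]
      if (length(unique(vals)) == 1) return("conserved")
      within_genus_varies <- any(vapply(unique(taxa$genus), function(g) {
        v <- vals[taxa$genus == g & taxa$rank == "species"]
        length(unique(v)) > 1
      }, logical(1)))
      if (within_genus_varies) "species" else "genus"
    }, character(1)))
  )
  if (is.null(screen_slot)) {
    # default: first conserved slot, the shared murine marker in the bundled
    # panel; NA when the panel has none
    conserved <- slots$slot[slots$resolution == "conserved"]
    screen_slot <- if (length(conserved) > 0) conserved[[1]] else NA_integer_
  }
  structure(
    list(taxa = taxa[c(need, slot_cols)], slots = slots,
         screen_slot = screen_slot, counterpart_mz = counterpart_mz),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d taxa x %d marker slots\n",
              nrow(x$taxa), nrow(x$slots)))
  print(x$taxa)
  invisible(x)
}

#' Load a marker panel from CSV
#'
#' The CSV schema is `taxon,rank,genus,slot1,...,slotN` with one row per
#' taxon and a numeric reference m/z in every slot cell.
#'
#' @param path Path to the panel CSV.
#' @inheritParams marker_panel
#' @return A `marker_panel`.
#' @export
load_panel <- function(path, legacy_letters = NULL, screen_slot = NULL,
                       counterpart_mz = 1459.7) {
  taxa <- readr::read_csv(path, show_col_types = FALSE)
  marker_panel(taxa, legacy_letters = legacy_letters,
               screen_slot = screen_slot, counterpart_mz = counterpart_mz)
}

#' The bundled murine rodent marker panel
#'
#' Nine collagen peptide marker slots for five murine taxa: *Rattus
#' norvegicus*, *R. rattus*, *Apodemus* (the *A. sylvaticus* /
#' *A. flavicollis* pair, unresolvable at species level and therefore carried
#' as one genus-level row), *Micromys* and *Mus*. Slot 8 separates the two
#' rat species (2987.5 vs 2957.5); slot 2 (1443.7) is the murine-specific
#' replacement of the conserved vertebrate marker at 1459.7 and drives the
#' murine screening flag. Letters A/B/D/F/G mark slots described for *Mus*
#' and *Rattus* in earlier fingerprinting work.
#'
#' @return A `marker_panel`.
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  path <- system.file("extdata", "murine_panel.csv", package = "zoomscreen",
                      mustWork = TRUE)
  load_panel(
    path,
    legacy_letters = c("A", NA, NA, "B", "D", NA, "F", "G", NA),
    screen_slot = 2, counterpart_mz = 1459.7
  )
}

# Long form: one row per taxon x slot.
panel_long <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  tidyr::pivot_longer(panel$taxa, dplyr::starts_with("slot"),
                      names_to = "column", values_to = "reference_mz") |>
    dplyr::left_join(panel$slots[c("slot", "column")], by = "column") |>
    dplyr::select("taxon", "rank", "genus", "slot", "reference_mz")
}

# Slots whose reference value for `taxon` is unique across the whole panel;
# these are the slots that can support a species-level call.
diagnostic_slots <- function(panel, taxon) {
  long <- panel_long(panel)
  me <- long[long$taxon == taxon, ]
  others <- long[long$taxon != taxon, ]
  vapply(seq_len(nrow(me)), function(i) {
    slot <- me$slot[[i]]
    !me$reference_mz[[i]] %in% others$reference_mz[others$slot == slot]
  }, logical(1)) |> (\(u) me$slot[u])()
}

# All reference masses in the panel (plus the vertebrate counterpart), used
# by the simulator's background exclusion zones.
panel_masses <- function(panel) {
  sort(unique(c(panel_long(panel)$reference_mz,
                if (!is.na(panel$counterpart_mz)) panel$counterpart_mz)))
}
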