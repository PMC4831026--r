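#' Singly protonated monoisotopic peptide mass
#'
#' Computes the \[M+H\]+ m/z of a peptide: the sum of its monoisotopic residue
#' masses, plus water, plus one proton, plus the mass shifts of any
#' hydroxylations (+15.9949 Da each, on Pro/Lys) and deamidations
#' (+0.9840 Da each, on Asn/Gln). This is the convention in which collagen
#' peptide-mass-fingerprint marker values are reported for MALDI-TOF spectra.
#'
#' Modification *positions* are not tracked, only counts: mass is
#' position-independent. Counts are validated against the number of
#' modifiable residues in the sequence (P+K for hydroxylation, N+Q for
#' deamidation).
#'
#' @param sequence Character vector of peptide sequences (one-letter codes).
#' @param n_hydroxylations,n_deamidations Integer counts of modifications,
#'   recycled along `sequence`.
#' @param masses A [mass_table()].
#' @return Numeric vector of m/z values (Da).
#' @examples
#' # The murine-specific COL1A1 marker, two hydroxyprolines:
#' peptide_mh("GAAGPPGATGFPGAAGR", n_hydroxylations = 2) # ~1443.70
#' # Its conserved vertebrate homologue:
#' peptide_mh("GSAGPPGATGFPGAAGR", n_hydroxylations = 2) # ~1459.69
#' @export
peptide_mh <- function(sequence, n_hydroxylations = 0, n_deamidations = 0,
                       masses = mass_table()) {
  stopifnot(inherits(masses, "mass_table"))
  n <- length(sequence)
  n_hydroxylations <- rep_len(as.integer(n_hydroxylations), n)
  n_deamidations <- rep_len(as.integer(n_deamidations), n)
  purrr::pmap_dbl(
    list(sequence, n_hydroxylations, n_deamidations),
    function(seq, noh, nde) {
      chars <- check_sequence(seq, masses)
      if (noh < 0 || nde < 0) abort("modification counts must be >= 0")
      n_pk <- sum(chars %in% c("P", "K"))
      n_nq <- sum(chars %in% c("N", "Q"))
      if (noh > n_pk) {
        abort(sprintf(
          "%d hydroxylations requested but \"%s\" has only %d P/K residues",
          noh, seq, n_pk
        ))
      }
      if (nde > n_nq) {
        abort(sprintf(
          "%d deamidations requested but \"%s\" has only %d N/Q residues",
          nde, seq, n_nq
        ))
      }
      sum(masses$residue_masses[chars]) + masses$water_mass +
        masses$proton_mass +
        noh * masses$mod_deltas[["hydroxylation"]] +
        nde * masses$mod_deltas[["deamidation"]]
    }
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine or arginine, except when
#' the following residue is proline (the classical trypsin rule used by
#' Mascot-style searches), and returns every fragment carrying between 0 and
#' `missed_cleavages` internal uncut K/R sites.
#'
#' @param sequence A single protein sequence string.
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   to allow (the search settings behind the marker panel used two).
#' @param masses A [mass_table()] used only to validate the alphabet.
#' @return A tibble with columns `peptide`, `start`, `end` (1-based positions
#'   in the protein) and `missed_cleavages`, ordered by start position then
#'   missed-cleavage count.
#' @examples
#' tryptic_digest("AKGR")           # AK + GR
#' tryptic_digest("AKPGR")          # KP bond is not cleaved
#' tryptic_digest("MKWVTFISLLR", missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0, masses = mass_table()) {
  chars <- check_sequence(sequence, masses)
  missed_cleavages <- as.integer(missed_cleavages)
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0")
  n <- length(chars)
  # cut points: after position i when chars[i] in K/R and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else integer())
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_frag <- length(starts)
  out <- purrr::map_dfr(seq_len(n_frag), function(i) {
    j_max <- min(n_frag, i + missed_cleavages)
    purrr::map_dfr(i:j_max, function(j) {
      tibble(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i],
        end = ends[j],
        missed_cleavages = j - i
      )
    })
  })
  dplyr::arrange(out, .data$start, .data$missed_cleavages)
}

#' Enumerate modification variants of a peptide
#'
#' Expands the full grid of hydroxylation and deamidation counts for one
#' peptide and computes the \[M+H\]+ m/z of each variant, mirroring how
#' variable modifications are enumerated in a database search.
#'
#' @param sequence A single peptide sequence string.
#' @param max_hydroxylations,max_deamidations Upper bounds on the counts;
#'   both are additionally capped by the number of modifiable residues
#'   (P+K, respectively N+Q) in the sequence.
#' @param masses A [mass_table()].
#' @return A tibble with columns `n_hydroxylations`, `n_deamidations`, `mz`,
#'   sorted by ascending m/z.
#' @examples
#' enumerate_variants("GEPGPSGLPGPPGER", max_hydroxylations = 5)
#' @export
enumerate_variants <- function(sequence, max_hydroxylations = 0,
                               max_deamidations = 0, masses = mass_table()) {
  chars <- check_sequence(sequence, masses)
  cap_oh <- min(max_hydroxylations, sum(chars %in% c("P", "K")))
  cap_de <- min(max_deamidations, sum(chars %in% c("N", "Q")))
  grid <- tidyr::expand_grid(
    n_hydroxylations = 0:cap_oh,
    n_deamidations = 0:cap_de
  )
  grid$mz <- peptide_mh(rep(sequence, nrow(grid)), grid$n_hydroxylations,
                        grid$n_deamidations, masses)
  dplyr::arrange(grid, .data$mz)
}

#' Digest proteins from a FASTA file into modified tryptic peptides
#'
#' Reads one or more protein sequences from FASTA, digests each with
#' [tryptic_digest()] and expands modification variants with
#' [enumerate_variants()].
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @param missed_cleavages Maximum missed cleavages (default 2).
#' @param max_hydroxylations,max_deamidations Per-peptide modification caps.
#' @param min_length Drop peptides shorter than this many residues.
#' @param masses A [mass_table()].
#' @return A tibble with columns `protein`, `peptide`, `start`,
#'   `missed_cleavages`, `n_hydroxylations`, `n_deamidations`, `mz`.
#' @export
digest_fasta <- function(path, missed_cleavages = 2, max_hydroxylations = 0,
                         max_deamidations = 0, min_length = 1,
                         masses = mass_table()) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("digest_fasta() requires the Biostrings package")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(sprintf("no sequences found in '%s'", path))
  purrr::map_dfr(seq_along(seqs), function(i) {
    frags <- tryptic_digest(as.character(seqs[[i]]), missed_cleavages, masses)
    frags <- dplyr::filter(frags, nchar(.data$peptide) >= min_length)
    purrr::map_dfr(seq_len(nrow(frags)), function(k) {
      v <- enumerate_variants(frags$peptide[[k]], max_hydroxylations,
                              max_deamidations, masses)
      tibble(
        protein = names(seqs)[[i]],
        peptide = frags$peptide[[k]],
        start = frags$start[[k]],
        missed_cleavages = frags$missed_cleavages[[k]],
        n_hydroxylations = v$n_hydroxylations,
        n_deamidations = v$n_deamidations,
        mz = v$mz
      )
    })
  })
}
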